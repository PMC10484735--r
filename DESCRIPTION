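Package: ssbfil
Title: Single-Molecule Analysis of Cooperative SSB-ssDNA Filaments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of single-molecule experiments on
    single-stranded DNA binding protein (SSB) filaments, developed around the
    bacteriophage T4 gene 32 protein (gp32) system. Provides freely jointed
    chain and worm-like chain polymer elasticity models with least-squares
    fitting of force-extension curves, force binning and bare-ssDNA extension
    subtraction, multiphase decomposition of constant-force binding and
    dissociation traces, Bell-model force-dependent and bimolecular
    concentration-dependent rate fits, an ideal protein-DNA helix geometry
    model with derived filament parameters, AFM backbone-trace contour and
    tangent-correlation persistence analysis with integrated-volume
    estimation, and seeded synthetic-data generators so that every stage of
    the pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
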