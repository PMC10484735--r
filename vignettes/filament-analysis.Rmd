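---
title: "Models and methods: quantifying cooperative SSB-ssDNA filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying cooperative SSB-ssDNA filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbfil)
```

## The system and the measurements

Single-stranded DNA binding proteins (SSBs) such as bacteriophage T4 gp32
coat transiently exposed ssDNA during replication. gp32 binds with an
occluded site size of about 7 nt and, through N-terminal protein-protein
contacts, polymerizes into cooperative filaments that helically wind the
ssDNA, shortening its effective contour while stiffening it dramatically.
Two kinds of single-molecule measurement probe this system:

* **Optical tweezers** on a long (~8.1 knt) ssDNA tether record
  force-extension curves (FECs) during slow stretch/release, and
  extension-vs-time traces while the tether is held at constant force and
  the free-protein concentration is stepped.
* **AFM imaging** of deposited complexes yields traced backbone coordinates
  (contour length, bending statistics) and height images (integrated
  molecular volume).

`ssbfil` implements the full quantitative pipeline for these data, plus
seeded generators that emulate every input class with known ground truth, so
each stage is testable without experimental recordings.

## Polymer elasticity

Bare ssDNA and noncooperatively coated ssDNA behave as a freely jointed
chain (FJC). With Kuhn length $b = 2p$ and total contour $L_c$:

$$x(F) = L_c\left[\coth\frac{Fb}{k_BT} - \frac{k_BT}{Fb}\right]
  \left(1 + \frac{F}{S}\right)$$

The enthalpic factor $(1 + F/S)$ is off by default: fits are restricted to
forces below 10 pN where backbone stretching is negligible, and the data
that motivated this package were fit inextensibly. `fjc_extension()`
evaluates the $F = 0$ limit explicitly (0 nm) and uses a series expansion of
the Langevin function below $Fb/k_BT = 10^{-4}$ to avoid cancellation.

Cooperative filaments are continuously flexible and follow the worm-like
chain (WLC) in the Marko-Siggia interpolation, with $z = x/L_c$:

$$F(z) = \frac{k_BT}{p}\left[\frac{1}{4(1-z)^2} - \frac14 + z\right]$$

`wlc_extension()` inverts this by bracketed root finding on
$z \in [0, 1-10^{-12}]$ (Brent's method, tolerance $10^{-12}$, two Newton
polish steps — the same bracket and a tighter tolerance than the
bisection-Newton scheme this replaces).

`fit_fjc()` (window 10 pN) and `fit_wlc()` (window 5 pN) estimate the
contour length per nucleotide and the persistence length by unweighted
least squares on extension, using the `nls` port algorithm, which converges
cleanly on zero-residual synthetic curves. The substrate length in
nucleotides must be known (it is degenerate with the contour per
nucleotide); it travels in the curve metadata.

Binned extension-change curves (`bin_fec()`, `extension_change()`) use
left-closed 1 pN bins keyed by their integer lower edge, report the SEM per
bin, and propagate SEMs in quadrature when the bare-ssDNA curve is
subtracted. Singleton bins carry an `NA` SEM, which the subtraction treats
as zero.

Thermal energy defaults to $k_BT$ = 4.11 pN nm (298 K) — the measurement
temperature was not stated for the motivating data — and is configurable
through `sm_constants()`.

## Kinetic decomposition

At constant force, protein binding produces up to three sequential phases
of extension change: a fast compaction (amplitude $\Delta x_+^1$, rate
$k_+^1$, from winding upon initial cluster formation) followed by two
kinetically distinct elongations ($\Delta x_+^2, k_+^2$ and
$\Delta x_+^3, k_+^3$, from filament unwinding as more protein packs in).
`decompose_binding_trace()`:

1. smooths with a centered 1 s moving average and estimates the noise SD
   from the first-difference MAD (insensitive to the slow signal);
2. locates the global minimum of the smoothed trace; if it is an interior
   point more than 3 noise SD below both endpoints, the trace is split
   there (the published analysis segments such traces by eye; the
   3-SD depth criterion is this package's reproducible replacement);
3. fits a single-exponential approach before the minimum and a two-rate
   decaying exponential after it, then refines the full three-phase model
   $x(t) = x_0 - \Delta x_1(1-e^{-k_1t}) + \Delta x_2(1-e^{-k_2t}) +
   \Delta x_3(1-e^{-k_3t})$ globally from those starting values. The
   refinement matters: the raw segment split assigns the elongation that
   has already begun before the minimum to the compaction phase, biasing
   $\Delta x_+^1$ by several percent;
4. on monotonic traces, compares one- against two-rate fits with a residual
   F-test at $\alpha = 0.05$; a phase is reported present only if its
   amplitude exceeds 3 noise SD, and two-rate fits whose rates are within
   1.5x fall back to one rate.

A single monotone elongation is assigned to the slow, equilibrating phase
($\Delta x_+^3$); this matches the concentration regime in which only the
slow phase survives.

Dissociation traces (`decompose_dissociation_trace()`) are classified among
pure linear (zeroth-order dissociation from cluster ends), single decaying
exponential (noncooperative dissociation along the whole substrate), and
their sum, by corrected AIC. Two deliberate additions to plain AICc:

* among candidates within $\Delta\mathrm{AICc} < 2$ the most parsimonious
  model wins (the standard "substantial support" rule), with an
  `ambiguous` flag;
* an exponential component is unsupported if its fitted rate is below
  $2/\mathrm{duration}$ — a decay that slow is indistinguishable from a
  line inside the window — or its amplitude below twice the noise SD.

Without these guards, pure-linear traces sprout spurious exponential
components in roughly a tenth of noisy replicates, because the extra
component can mimic a line at vanishing rate. With them, model selection is
correct in at least 95 of 100 seeded replicates per regime at the package's
stated noise scales.

Because the units of the "initial dissociation rate" from the linear phase
are convention-dependent, both the raw slope (nm/s) and the slope
normalized by the total extension change (s$^{-1}$) are reported.

Rate models:

* **Bell**: $k(F) = k_0 e^{F\Delta x / k_BT}$, fit as a weighted linear
  regression of $\ln k$ on $F$ (weights $(k/\sigma)^2$, the inverse
  variance of $\ln k$); $\Delta x$ keeps its sign. With
  $\Delta x = 0.105$ nm the predicted rate ratio over 10-60 pN is
  $e^{50 \cdot 0.105/4.11} \approx 3.6$.
* **Bimolecular**: $k_{obs} = c\,k_{on} + k_{off}$ by weighted linear
  regression, $K_D = k_{off}/k_{on}$ (`compute_kd()`); 0.11/0.0024 gives
  ~46 nM.
* **Two-step**: the motivating analysis names a "two-step reaction model"
  without writing it down. The minimal form with the stated phenomenology
  (linear at low concentration, asymptotic at high) is the steady-state
  sequential scheme $k(c) = c\,k_b k_c/(c\,k_b + k_c)$, adopted here. When
  the data never leave the linear regime, $k_c$ is flagged unbounded and
  $k_b$ reduces to the bimolecular slope (agreement to 0.1% on the same
  series).

## Helix geometry

An ideal helix wound from inextensible ssDNA conserves arc length per turn,
$\left(\rho L/L'\right)^2 = \rho^2 + (2\pi R)^2$, equivalently

$$\frac{R}{\rho} = \frac{1}{2\pi}\sqrt{\left(\frac{L}{L'}\right)^2 - 1}$$

with $L$ the bare contour per nt, $L'$ the wound (axial) contour per nt,
$R$ the filament radius and $\rho$ the pitch. `helix_parameters()` derives
pitch, nt per turn, proteins per turn $N$, twist per protein
$\alpha = 360°/N$, site size, axial/arc lengths per protein and protein
densities (both per nm of axis and per nt, since the published density
panel is ambiguous between the two). Two conventions coexist in the source
analysis and both are exposed: the *relaxed* convention fixes the site size
(7 nt) and is used for the worked example at the most compact state
($L' = 0.41$, giving $\approx 34$ nt/turn, $N \approx 4.9$,
$\alpha \approx 73°$, 3.9 nm of ssDNA and 2.8 nm of axis per protein); the
*axial* convention fixes the protein's axial footprint $h$ and is used by
`helix_sweep()` across a concentration series, where the shrinking site
size $bss = h/L'$ (down to 5 nt at $L' = L$) expresses protein
overcrowding. The unwound limit is represented by an infinite-pitch
sentinel with defined limits (ratio 0, twist 0) rather than an error.

Note the printed pitch of the motivating analysis (13.9 nm) differs by
~1.5% from direct evaluation with the rounded inputs (14.2 nm), implying
unrounded intermediates; tests compare within the printed uncertainty.

`filament_radius_from_volumes()` implements the cylinder-volume comparison
$r_{ss} = \sqrt{V_{ss}L_{ds}/(V_{ds}L_{ss})}\, r_{ds}$ against the dsDNA
reference (radius 1 nm, rise 0.34 nm/bp). `turnover_requirement()` performs
the replication arithmetic: at a 500 nt/s fork and 7 nt per protein, ~71
proteins/s must vacate the template; spread over the ~300 proteins on a
2000 nt Okazaki fragment this demands ~0.25 s$^{-1}$ per protein.

## AFM backbone statistics

`trace_contour_length()` sums segment lengths; contour is stable to ±0.5%
across resample steps of 2-10 nm for smooth fixtures. For bending
statistics, traces are resampled to a uniform arc step (default 5 nm, the
scale of a typical scan pixel; the source analysis does not state its
discretization) and `tangent_correlation()` averages
$\cos(\theta_{i+k} - \theta_i)$ per molecule, then across molecules with
equal weight (a pooled-pairs mode is available; the equal-molecule reading
follows the phrase "averaged over all molecules"). A 2D worm-like chain
decays as $\langle\cos\theta(L)\rangle = e^{-L/2p}$, which
`fit_persistence_2d()` inverts as a one-parameter fit; non-decaying
profiles return an unbounded flag rather than a number.

One numerical caveat, documented because it shapes the tests: tangents are
estimated from resampled *chords*. Chord directions average the underlying
tangents over one step $s$, which multiplies the ideal profile by a
constant factor $\approx e^{s/6p}$ (for a continuous chain) — a few percent
at $s = 5$ nm, $p = 20$ nm. It inflates the profile at all separations but
barely perturbs the fitted $p$ (the constant is mostly orthogonal to the
decay). The generator's discrete chains have exactly
$\langle\cos\theta\rangle = e^{-L/2p}$ between their own segments, so
ensemble tests set the generator's `arc_step` equal to the resample step,
where the estimator is exactly unbiased.

Loops preserved during deposition anticorrelate tangents, so persistence is
measured on `longest_loopfree_segment()`: self-contacts are point pairs
within a contact radius (default 4 nm, about twice the measured filament
radius) whose arc separation exceeds four contact radii, and the longest
contiguous contact-free run survives.

`integrated_volume()` sums heights above background times pixel area. The
background defaults to the image median (molecules occupy a small area
fraction; the source's background method is unstated) and can be
overridden; an optional noise floor suppresses the positive half of the
background noise, which otherwise dominates small molecules integrated over
a large frame. `trace_afm_skeleton()` recovers backbones from *synthetic*
images only: threshold at half maximum, non-maximum suppression across the
ridge, greedy nearest-neighbor chaining.

## The synthetic world

Generators take an explicit integer seed, restore the caller's RNG state,
and embed their ground truth in the output metadata. What they emulate —
and what they deliberately do not:

* `gen_fec()`: forward FJC/WLC plus additive Gaussian extension noise
  (optical-trap-like). No drift, no hysteresis, no force-dependent noise.
* `gen_binding_trace()`: the canonical sum of saturating exponentials at
  default 10 Hz sampling and 5 nm noise (the visual scale of published
  traces). The canonical test regimes use a 3200 nm tether (8.1 knt at
  ~0.4 nm/nt), triphasic amplitudes (200, 50, 100) nm at
  (0.5, 0.05, 0.01) s$^{-1}$, and noise at 2% of the largest amplitude, the
  level the recovery invariants stipulate. The generator reproduces fitted
  functional forms, not binding mechanism: no lattice occupancy, no
  cooperativity model.
* `gen_dissociation_trace()`: linear-plus-exponential with zeroable
  components.
* `gen_chain_2d()`: discrete 2D WLC (Gaussian turning angles of variance
  step/p). Real deposited molecules additionally show loops, overlaps and
  surface-equilibration artifacts; only loops have an analysis counterpart
  here.
* `gen_afm_image()`: rasterized backbone, Gaussian blur as a tip-convolution
  proxy (sum-preserving, so injected volume is conserved), Gaussian
  background noise. No true dilation-style tip geometry, no scan-line
  artifacts.
* `gen_rate_series()`: forward rate model with multiplicative log-normal
  noise (rates are positive). Recovery tests use sdlog 0.01-0.02, emulating
  points that are replicate-averaged SEMs; at that level the statistical
  parameter uncertainty is below ~2%, so a 5% recovery check tests
  estimator bias rather than noise luck.

A green recovery test therefore establishes that each estimator inverts its
own generating model accurately at realistic signal-to-noise — not that it
would be unbiased against every instrumental artifact of real recordings.

## Numerical choices and limitations

* All nonlinear fits: `nls` with the port algorithm, bounded below at
  physical zeros, 500 iterations; fit failures raise classed conditions
  (`ssbfil_fit_failure`, `ssbfil_insufficient_data`,
  `ssbfil_domain_error`).
* Fits are unweighted in extension unless per-point uncertainties are
  supplied (none of the stated analyses weight them).
* Rates are returned in descending order; two-rate fits with separation
  below 1.5x collapse to one rate with a flag.
* Reports from `run_pipeline()` contain no timestamps, so identical inputs
  and configuration yield byte-identical JSON.
* Out of scope: dsDNA overstretching and force-melting, twistable WLC,
  hysteresis modelling of stretch-release cycles, hidden-Markov or Bayesian
  changepoint inference, force-jump protocols beyond treating each
  constant-force segment independently, tip deconvolution, and
  general-purpose tracing of experimental AFM images.

## A worked example

```{r helix}
hp <- helix_parameters(R = 2.1, L = 0.56, L_prime = 0.41, bss_ref = 7)
hp

# the same filament, fully unwound, in the axial convention
helix_parameters(R = 2.1, L = 0.56, L_prime = 0.56, h = 2.8)$bss

# simple on-off binding kinetics
compute_kd(k_off = 0.11, k_on = 0.0024)
```

```{r recovery}
fec <- gen_fec(polymer_params(0.510, 8100, 1.9), "fjc",
               seq(0.5, 10, length.out = 50), seed = 7, noise_sd = 1)
fit_fjc(fec)
```
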