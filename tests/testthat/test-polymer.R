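test_that("FJC extension matches the closed form and its limits", {
  # Fb/kBT = 1 for b = 2p = 2 nm at F = kBT/2; coth(1) - 1 = 0.3130
  p <- polymer_params(1, 100, 1)
  expect_equal(fjc_extension(sm_constants()$kBT / 2, p), 31.3035285,
               tolerance = 1e-6)
  # saturation: extension approaches the full contour
  expect_equal(fjc_extension(1e7, p), 100, tolerance = 1e-5)
  # explicit zero-force limit; negative force is a domain error
  expect_identical(fjc_extension(0, p), 0)
  expect_error(fjc_extension(-1, p), class = "ssbfil_domain_error")
  # enthalpic factor multiplies by (1 + F/S)
  pe <- polymer_params(1, 100, 1, stretch_modulus = 800)
  f <- 5
  expect_equal(fjc_extension(f, pe), fjc_extension(f, p) * (1 + f / 800))
})

test_that("WLC force matches Marko-Siggia and inverts to 1e-10", {
  pp <- polymer_params(0.41, 8100, 20)
  expect_identical(wlc_force(0, pp), 0)
  expect_equal(wlc_force(0.5, pp), 1.25 * 4.11 / 20, tolerance = 1e-12)
  expect_error(wlc_force(1, pp), class = "ssbfil_domain_error")
  Lc <- 0.41 * 8100
  for (z in c(0.01, 0.1, 0.5, 0.9, 0.99)) {
    f <- wlc_force(z, pp)
    expect_equal(wlc_extension(f, pp) / Lc, z, tolerance = 1e-9)
  }
})

test_that("both model extensions increase strictly with force", {
  grid <- seq(0.1, 60, length.out = 120)
  for (par in list(polymer_params(0.56, 8100, 0.75),
                   polymer_params(0.51, 8100, 1.9))) {
    expect_true(all(diff(fjc_extension(grid, par)) > 0))
  }
  for (par in list(polymer_params(0.41, 8100, 20),
                   polymer_params(0.49, 8100, 20))) {
    expect_true(all(diff(wlc_extension(grid, par)) > 0))
  }
})

test_that("noiseless generated curves round-trip through the fits", {
  fec <- gen_fec(polymer_params(0.510, 8100, 1.9), "fjc",
                 seq(0.5, 10, length.out = 40), seed = 1)
  ft <- fit_fjc(fec)
  expect_rel(ft$params$contour_per_nt, 0.510, 1e-6)
  expect_rel(ft$params$persistence, 1.9, 1e-6)
  expect_lt(ft$residual_rms, 1e-6)
  expect_equal(ft$force_window[2], 10)

  few <- gen_fec(polymer_params(0.41, 8100, 20), "wlc",
                 seq(0.2, 5, length.out = 40), seed = 1)
  fw <- fit_wlc(few)
  expect_rel(fw$params$contour_per_nt, 0.41, 1e-6)
  expect_rel(fw$params$persistence, 20, 1e-6)
})

test_that("fits tolerate 1 nm Gaussian noise at 50 samples", {
  fec <- gen_fec(polymer_params(0.510, 8100, 1.9), "fjc",
                 seq(0.5, 10, length.out = 50), seed = 7, noise_sd = 1)
  ft <- fit_fjc(fec)
  expect_rel(ft$params$contour_per_nt, 0.510, 0.02)
  expect_rel(ft$params$persistence, 1.9, 0.10)

  few <- gen_fec(polymer_params(0.41, 8100, 20), "wlc",
                 seq(0.5, 5, length.out = 50), seed = 8, noise_sd = 1)
  fw <- fit_wlc(few)
  expect_rel(fw$params$contour_per_nt, 0.41, 0.02)
  expect_rel(fw$params$persistence, 20, 0.10)
})

test_that("fits reject windows with fewer than 5 samples", {
  fec <- force_extension_curve(c(2, 5, 8, 15, 20, 30),
                               c(1000, 1500, 1800, 2500, 2700, 3000),
                               meta = list(n_nt = 8100))
  expect_error(fit_fjc(fec), class = "ssbfil_insufficient_data")
  high <- force_extension_curve(seq(6, 30, 2), seq(2000, 3200, 100),
                                meta = list(n_nt = 8100))
  expect_error(fit_wlc(high), class = "ssbfil_insufficient_data")
})

test_that("force binning uses left-closed 1 pN bins", {
  single <- force_extension_curve(3.2, 1500)
  b1 <- bin_fec(single)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$bin, 3)
  expect_equal(b1$n, 1)

  # two points per bin: means are pairwise averages
  fec <- force_extension_curve(c(1.2, 1.8, 2.2, 2.8),
                               c(100, 110, 200, 220))
  b <- bin_fec(fec)
  expect_equal(b$bin, c(1, 2))
  expect_equal(b$force_mean, c(1.5, 2.5))
  expect_equal(b$extension_mean, c(105, 210))

  # constant-extension bin has zero SEM
  cst <- force_extension_curve(c(4.1, 4.9), c(300, 300))
  expect_equal(bin_fec(cst)$extension_sem, 0)
})

test_that("extension change subtracts the bare curve per force bin", {
  grid <- seq(0.5, 30, by = 0.25)
  bare <- gen_fec(polymer_params(0.56, 8100, 0.75), "fjc", grid, seed = 1)
  expect_true(all(abs(extension_change(bare, bare)$dx) < 1e-12))

  shifted <- force_extension_curve(bare$force, bare$extension + 10)
  expect_equal(extension_change(shifted, bare)$dx,
               rep(10, length(unique(floor(grid)))))

  # cooperative complex (WLC, shorter contour, stiffer) vs bare ssDNA FJC:
  # elongated at low force, compacted at high force
  complexed <- gen_fec(polymer_params(0.41, 8100, 20), "wlc", grid, seed = 1)
  dx <- extension_change(complexed, bare)
  expect_gt(dx$dx[dx$bin == 2], 0)
  expect_lt(dx$dx[dx$bin == 25], 0)

  # disjoint force ranges are an error
  lo <- force_extension_curve(c(1.1, 1.5), c(10, 20))
  hi <- force_extension_curve(c(7.1, 7.5), c(10, 20))
  expect_error(extension_change(lo, hi), class = "ssbfil_domain_error")
})
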