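test_that("exponential fits recover generating parameters exactly", {
  t <- seq(0, 60, 0.1)
  x <- 3000 - 200 * exp(-0.11 * t)
  f1 <- fit_exponential(list(time = t, extension = x), 1)
  expect_rel(f1$amplitudes[1], 200, 1e-6)
  expect_rel(f1$rates[1], 0.11, 1e-6)
  expect_rel(f1$x_eq, 3000, 1e-8)

  t2 <- seq(0, 600, 0.5)
  x2 <- 2500 - 120 * exp(-0.3 * t2) - 80 * exp(-0.01 * t2)
  f2 <- fit_exponential(list(time = t2, extension = x2), 2)
  expect_equal(f2$n_rates, 2L)
  expect_rel(f2$rates[1], 0.3, 1e-4)
  expect_rel(f2$rates[2], 0.01, 1e-4)
  expect_rel(f2$amplitudes[1], 120, 1e-4)
  expect_rel(f2$amplitudes[2], 80, 1e-4)

  cst <- fit_exponential(list(time = t, extension = rep(42, length(t))), 1)
  expect_equal(cst$amplitudes, 0)
  expect_equal(cst$x_eq, 42)
})

test_that("unresolved rate pairs fall back to a single rate", {
  t <- seq(0, 100, 0.1)
  x <- 1000 - 150 * exp(-0.1 * t)  # noiseless single exponential
  f <- fit_exponential(list(time = t, extension = x), 2)
  expect_equal(f$n_rates, 1L)
  expect_true(f$fallback)
})

test_that("binding decomposition recovers all three regimes", {
  # noiseless traces: near-exact parameter recovery
  for (nm in names(binding_regimes)) {
    reg <- binding_regimes[[nm]]
    tr <- gen_regime_trace(reg, seed = 1, noise_sd = 0)
    d <- decompose_binding_trace(tr)
    expect_equal(d$structure, reg$structure, label = nm)
    if (reg$amplitudes[1] > 0) {
      expect_rel(-d$dx1, reg$amplitudes[1], 1e-3)
      expect_rel(d$k1, reg$rates[1], 1e-3)
    } else {
      expect_identical(d$dx1, 0)
    }
    if (reg$amplitudes[2] > 0) {
      expect_rel(d$dx2, reg$amplitudes[2], 1e-3)
      expect_rel(d$k2, reg$rates[2], 1e-3)
    }
    if (reg$amplitudes[3] > 0) {
      expect_rel(d$dx3, reg$amplitudes[3], 1e-3)
      expect_rel(d$k3, reg$rates[3], 1e-3)
    }
  }

  # noisy triphasic traces (noise 2% of the largest amplitude): median
  # recovery over fixed seeds within 5% on amplitudes and 10% on rates
  reg <- binding_regimes$triphasic
  errs <- sapply(21:25, function(s) {
    d <- decompose_binding_trace(gen_regime_trace(reg, seed = s))
    expect_true(d$k1 >= d$k2 && d$k2 >= d$k3)
    c(abs(c(-d$dx1, d$dx2, d$dx3) - reg$amplitudes) / reg$amplitudes,
      abs(c(d$k1, d$k2, d$k3) - reg$rates) / reg$rates)
  })
  med <- apply(errs, 1, stats::median)
  expect_true(all(med[1:3] < 0.05))
  expect_true(all(med[4:6] < 0.10))
})

test_that("dissociation decomposition selects and fits the right model", {
  reg <- dissociation_regimes$linear
  d <- decompose_dissociation_trace(gen_dissociation_regime(reg, seed = 31))
  expect_equal(d$mode, "linear")
  expect_rel(d$linear_slope, reg$slope, 0.01)

  reg <- dissociation_regimes$linear_plus_exponential
  d <- decompose_dissociation_trace(gen_dissociation_regime(reg, seed = 32))
  expect_equal(d$mode, "linear_plus_exponential")
  expect_rel(d$linear_slope, reg$slope, 0.05)
  expect_rel(d$exp_amplitude, reg$exp_amp, 0.05)
  expect_rel(d$exp_rate, reg$exp_rate, 0.05)

  reg <- dissociation_regimes$exponential
  d <- decompose_dissociation_trace(gen_dissociation_regime(reg, seed = 33))
  expect_equal(d$mode, "exponential")
  expect_rel(d$exp_amplitude, reg$exp_amp, 0.05)
  expect_rel(d$exp_rate, reg$exp_rate, 0.05)

  # flat trace: linear with (near-)zero slope, no exponential component
  flat <- gen_dissociation_trace(0, 0, 0, 100, seed = 34, noise_sd = 0.5)
  d <- decompose_dissociation_trace(flat)
  expect_equal(d$mode, "linear")
  expect_lt(abs(d$linear_slope), 0.01)
})

test_that("Bell fit recovers signed transition lengths exactly", {
  grid <- seq(10, 60, 5)
  for (dx in c(-0.105, 0.112)) {
    rs <- gen_rate_series("bell", list(k0 = 1, delta_x = dx), grid, seed = 1)
    bf <- fit_bell(rs)
    expect_rel(bf$delta_x, dx, 1e-9)
    expect_rel(bf$k0, 1, 1e-9)
  }
  # force-independent rates give delta_x = 0
  flat <- rate_series(grid, rep(0.2, length(grid)))
  expect_equal(fit_bell(flat)$delta_x, 0)
  expect_error(fit_bell(rate_series(c(10, 20), c(1, 0.9))),
               class = "ssbfil_insufficient_data")
})

test_that("Bell delta_x is invariant to rescaling all rates", {
  rs <- gen_rate_series("bell", list(k0 = 0.5, delta_x = -0.105),
                        seq(10, 60, 5), seed = 5, noise_sd = 0.05)
  b1 <- fit_bell(rs)
  rs2 <- rate_series(rs$abscissa, rs$rates * 7, rs$uncertainties * 7)
  b2 <- fit_bell(rs2)
  expect_equal(b2$delta_x, b1$delta_x, tolerance = 1e-10)
  expect_rel(b2$k0, 7 * b1$k0, 1e-9)
})

test_that("bimolecular fit yields on/off rates and K_D", {
  cc <- c(10, 25, 50, 100, 200, 300)
  rs <- gen_rate_series("bimolecular", list(k_on = 0.0024, k_off = 0.11),
                        cc, seed = 1)
  bf <- fit_bimolecular(rs)
  expect_rel(bf$k_on, 0.0024, 1e-9)
  expect_rel(bf$k_off, 0.11, 1e-9)
  expect_rel(bf$K_D, 0.11 / 0.0024, 1e-9)

  # zero off-rate: K_D = 0
  z <- rate_series(cc, cc * 0.0024)
  expect_equal(fit_bimolecular(z)$K_D, 0, tolerance = 1e-12)

  # two exact points define the line exactly
  two <- rate_series(c(50, 150), c(50, 150) * 0.002 + 0.05)
  bt <- fit_bimolecular(two)
  expect_equal(bt$k_on, 0.002, tolerance = 1e-12)
  expect_equal(bt$k_off, 0.05, tolerance = 1e-12)
})

test_that("two-step fit deconvolves binding and compaction rates", {
  cc <- c(5, 25, 100, 300, 1000)
  rs <- gen_rate_series("two_step", list(k_b = 0.003, k_c = 1.5), cc,
                        seed = 1)
  tf <- fit_two_step(rs)
  expect_rel(tf$k_b, 0.003, 1e-6)
  expect_rel(tf$k_c, 1.5, 1e-6)
  # the fitted curve asymptotes to k_c
  expect_rel(two_step_rate(1e9, tf$k_b, tf$k_c), tf$k_c, 1e-4)

  # purely linear series: k_c unbounded, slope agrees with the
  # bimolecular fit to 0.1%
  lin <- rate_series(cc, cc * 0.003)
  tl <- fit_two_step(lin)
  expect_true(tl$flag_kc_unbounded)
  bl <- fit_bimolecular(lin)
  expect_rel(tl$k_b, bl$k_on, 1e-3)
})

test_that("K_D arithmetic", {
  expect_equal(compute_kd(0.11, 0.0024), 45.83333, tolerance = 1e-6)
  expect_equal(compute_kd(0, 5), 0)
  expect_equal(compute_kd(1, 1), 1)
  expect_error(compute_kd(0.1, 0), class = "ssbfil_domain_error")
})

test_that("trace constructors validate their invariants", {
  expect_error(time_extension_trace(c(0, 1, 1), c(1, 2, 3)),
               class = "ssbfil_domain_error")
  expect_error(time_extension_trace(0:2, 1:2), class = "ssbfil_domain_error")
  expect_error(rate_series(1:3, c(1, -1, 2)), class = "ssbfil_domain_error")
  expect_error(gen_binding_trace(100, c(10, 20, 5), c(0.1, 0.5, 0.01),
                                 10, seed = 1),
               class = "ssbfil_domain_error")
})
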