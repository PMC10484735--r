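# canonical synthetic regimes shared between unit and acceptance tests;
# amplitudes/rates sit at the scales of constant-force gp32 traces

binding_regimes <- list(
  triphasic = list(x0 = 3200, amplitudes = c(200, 50, 100),
                   rates = c(0.5, 0.05, 0.01), duration = 600, dt = 0.25,
                   noise_sd = 4, structure = "triphasic"),
  biphasic_elongation = list(x0 = 2000, amplitudes = c(0, 120, 80),
                             rates = c(0, 0.1, 0.01), duration = 600,
                             dt = 0.25, noise_sd = 4,
                             structure = "biphasic_elongation"),
  monophasic_compaction = list(x0 = 3200, amplitudes = c(150, 0, 0),
                               rates = c(0.4, 0, 0), duration = 60,
                               dt = 0.1, noise_sd = 4,
                               structure = "monophasic_compaction")
)

gen_regime_trace <- function(regime, seed, noise_sd = regime$noise_sd) {
  gen_binding_trace(regime$x0, regime$amplitudes, regime$rates,
                    duration = regime$duration, seed = seed,
                    dt = regime$dt, noise_sd = noise_sd)
}

dissociation_regimes <- list(
  linear = list(slope = -0.5, exp_amp = 0, exp_rate = 0, duration = 200,
                dt = 0.2, noise_sd = 2, mode = "linear"),
  linear_plus_exponential = list(slope = -0.3, exp_amp = 80, exp_rate = 0.05,
                                 duration = 300, dt = 0.2, noise_sd = 2,
                                 mode = "linear_plus_exponential"),
  exponential = list(slope = 0, exp_amp = 100, exp_rate = 0.02,
                     duration = 250, dt = 0.2, noise_sd = 2,
                     mode = "exponential")
)

gen_dissociation_regime <- function(regime, seed, noise_sd = regime$noise_sd) {
  gen_dissociation_trace(regime$slope, regime$exp_amp, regime$exp_rate,
                         duration = regime$duration, seed = seed,
                         dt = regime$dt, noise_sd = noise_sd)
}

# path with one crossing: long flank, loop returning to the crossing point,
# shorter flank; the longest loop-free run is the first flank
crossing_trace <- function(flank1 = 100, flank2 = 60, loop_radius = 10) {
  a <- seq(0.3, 2 * pi - 0.3, length.out = 18)
  pts <- rbind(cbind(seq(0, flank1, 2), 0),
               cbind(flank1 + loop_radius * sin(a),
                     loop_radius - loop_radius * cos(a)),
               cbind(seq(flank1 + 2, flank1 + flank2, 2), 0))
  backbone_trace(pts[, 1], pts[, 2])
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
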