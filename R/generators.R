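#' Generate a synthetic force-extension curve
#'
#' Forward-evaluates the FJC or WLC model on a force grid and adds i.i.d.
#' Gaussian noise to the extension (optical-trap-like additive noise). The
#' generating parameters are recorded in the curve metadata as ground truth
#' for recovery tests.
#'
#' @param params A [polymer_params()] object.
#' @param model `"fjc"` or `"wlc"`.
#' @param force_grid Forces in pN.
#' @param noise_sd Extension noise SD in nm. Default 0.
#' @param seed Integer seed (required).
#' @param direction `"stretch"` or `"release"`.
#' @param constants A [sm_constants()] object.
#'
#' @return A [force_extension_curve()] whose `meta$truth` holds the
#'   generating parameters.
#' @export
gen_fec <- function(params, model = c("fjc", "wlc"), force_grid, seed,
                    noise_sd = 0, direction = "stretch",
                    constants = sm_constants()) {
  model <- match.arg(model)
  stopifnot(inherits(params, "polymer_params"), noise_sd >= 0)
  fwd <- switch(model, fjc = fjc_extension, wlc = wlc_extension)
  x <- fwd(force_grid, params, constants)
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(length(x), 0, noise_sd))
  }
  force_extension_curve(force_grid, x, direction = direction,
                        meta = list(n_nt = params$n_nt,
                                    truth = list(model = model,
                                                 contour_per_nt = params$contour_per_nt,
                                                 persistence = params$persistence,
                                                 stretch_modulus = params$stretch_modulus,
                                                 noise_sd = noise_sd,
                                                 seed = seed)))
}

#' Generate a synthetic constant-force binding trace
#'
#' The canonical three-phase binding response of ssDNA extension to protein
#' introduction: an initial compaction followed by two elongations,
#' `x(t) = x0 - dx1*(1 - exp(-k1 t)) + dx2*(1 - exp(-k2 t)) +
#' dx3*(1 - exp(-k3 t)) + noise`, with all amplitudes given as non-negative
#' magnitudes (zero amplitude switches a phase off). Noiselessly,
#' `x(Inf) - x0 = -dx1 + dx2 + dx3` exactly. Defaults emulate a trace at
#' 15 pN and 100 nM protein sampled at 10 Hz with 5 nm extension noise.
#'
#' @param x0 Initial extension in nm.
#' @param amplitudes Numeric vector `c(dx1, dx2, dx3)` of phase magnitudes
#'   in nm, all >= 0.
#' @param rates Numeric vector `c(k1, k2, k3)` in s^-1; must be descending
#'   over the phases whose amplitude is nonzero.
#' @param duration Trace duration in s.
#' @param seed Integer seed (required).
#' @param dt Sampling interval in s. Default 0.1.
#' @param noise_sd Extension noise SD in nm. Default 5.
#' @param force,concentration Recorded conditions.
#'
#' @return A [time_extension_trace()] with `phase = "binding"` and ground
#'   truth in `meta$truth`.
#' @export
gen_binding_trace <- function(x0, amplitudes, rates, duration, seed,
                              dt = 0.1, noise_sd = 5,
                              force = NA_real_, concentration = NA_real_) {
  stopifnot(length(amplitudes) == 3, length(rates) == 3,
            all(amplitudes >= 0), noise_sd >= 0, duration > 0, dt > 0)
  on_rates <- rates[amplitudes > 0]
  if (length(on_rates)) {
    if (any(!is.finite(on_rates)) || any(on_rates <= 0)) {
      stop_domain("rates of present phases must be positive")
    }
    if (is.unsorted(rev(on_rates), strictly = FALSE)) {
      stop_domain("rates must be descending across present phases (k1 >= k2 >= k3)")
    }
  }
  t <- seq(0, duration, by = dt)
  ph <- function(a, k) if (a > 0) a * (1 - exp(-k * t)) else rep(0, length(t))
  x <- x0 - ph(amplitudes[1], rates[1]) + ph(amplitudes[2], rates[2]) +
    ph(amplitudes[3], rates[3])
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  time_extension_trace(t, x, force = force, concentration = concentration,
                       phase = "binding",
                       meta = list(truth = list(x0 = x0,
                                                amplitudes = amplitudes,
                                                rates = rates,
                                                noise_sd = noise_sd,
                                                seed = seed)))
}

#' Generate a synthetic dissociation trace
#'
#' `x(t) = x0 + slope * t - exp_amp * exp(-exp_rate * t) + noise`; either
#' component can be zeroed to produce the pure-linear (cluster-end
#' dissociation) or pure-exponential (noncooperative dissociation) regimes.
#'
#' @param slope Linear slope in nm/s (recompaction negative).
#' @param exp_amp Exponential amplitude in nm (0 for none).
#' @param exp_rate Exponential rate in s^-1 (> 0 when `exp_amp != 0`).
#' @param duration Trace duration in s.
#' @param seed Integer seed (required).
#' @param x0 Baseline extension in nm. Default 3000.
#' @param dt Sampling interval in s. Default 0.1.
#' @param noise_sd Extension noise SD in nm. Default 5.
#' @param force,concentration Recorded conditions.
#'
#' @return A [time_extension_trace()] with `phase = "dissociation"` and
#'   ground truth in `meta$truth`.
#' @export
gen_dissociation_trace <- function(slope, exp_amp, exp_rate, duration, seed,
                                   x0 = 3000, dt = 0.1, noise_sd = 5,
                                   force = NA_real_,
                                   concentration = NA_real_) {
  stopifnot(noise_sd >= 0, duration > 0, dt > 0)
  if (exp_amp != 0 && (!is.finite(exp_rate) || exp_rate <= 0)) {
    stop_domain("exp_rate must be positive when an exponential component is present")
  }
  t <- seq(0, duration, by = dt)
  x <- x0 + slope * t
  if (exp_amp != 0) x <- x - exp_amp * exp(-exp_rate * t)
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  time_extension_trace(t, x, force = force, concentration = concentration,
                       phase = "dissociation",
                       meta = list(truth = list(x0 = x0, slope = slope,
                                                exp_amp = exp_amp,
                                                exp_rate = exp_rate,
                                                noise_sd = noise_sd,
                                                seed = seed)))
}

#' Generate a 2D worm-like chain backbone
#'
#' Discretized 2D WLC: successive turning angles are i.i.d. Gaussian with
#' mean 0 and variance `arc_step / persistence`, which yields the tangent
#' correlation `<cos theta(L)> = exp(-L / 2p)` in expectation. An infinite
#' persistence length produces a straight line.
#'
#' @param persistence Persistence length p in nm (may be `Inf`).
#' @param total_length Chain contour length in nm.
#' @param seed Integer seed (required).
#' @param arc_step Discretization step in nm, much smaller than p.
#'   Default 2.5.
#' @param initial_angle Starting tangent angle in radians. Default 0.
#' @param molecule_id Identifier.
#'
#' @return A [backbone_trace()] with ground truth in `meta$truth`.
#' @export
gen_chain_2d <- function(persistence, total_length, seed, arc_step = 2.5,
                         initial_angle = 0, molecule_id = NA_character_) {
  stopifnot(persistence > 0, total_length > 0, arc_step > 0)
  n_seg <- max(2L, round(total_length / arc_step))
  turns <- if (is.infinite(persistence)) {
    rep(0, n_seg - 1L)
  } else {
    with_seed(seed, stats::rnorm(n_seg - 1L, 0, sqrt(arc_step / persistence)))
  }
  ang <- initial_angle + cumsum(c(0, turns))
  x <- c(0, cumsum(arc_step * cos(ang)))
  y <- c(0, cumsum(arc_step * sin(ang)))
  backbone_trace(x, y, molecule_id = molecule_id,
                 meta = list(truth = list(persistence = persistence,
                                          total_length = n_seg * arc_step,
                                          arc_step = arc_step, seed = seed)))
}

## separable Gaussian blur with zero padding; kernel normalized so the
## integrated height is conserved away from the image edge
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_cols <- function(mm) {
    apply(mm, 2, function(v) {
      stats::convolve(c(rep(0, r), v, rep(0, r)), k, type = "filter")
    })
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Generate a synthetic AFM height image from a backbone trace
#'
#' Rasterizes the backbone at the given molecule height, applies a Gaussian
#' blur as a proxy for tip convolution (sum-preserving, so the injected
#' volume is conserved), and adds Gaussian background noise. The injected
#' integrated volume is recorded in the metadata. With `trace = NULL` a flat
#' (molecule-free) image of `dim_px` pixels is produced.
#'
#' @param trace A [backbone_trace()] in nm, or `NULL`.
#' @param seed Integer seed (required).
#' @param molecule_height Backbone height in nm. Default 2.
#' @param tip_sigma Tip-convolution Gaussian sigma in nm. Default 4.
#' @param pixel_size Pixel edge in nm. Default 2.
#' @param noise_sd Background height noise SD in nm. Default 0.02.
#' @param dim_px Image dimension (rows, cols) used when `trace` is `NULL`.
#'
#' @return An [afm_image()] with `background = 0` and
#'   `meta$truth$injected_volume` in nm^3.
#' @export
gen_afm_image <- function(trace, seed, molecule_height = 2, tip_sigma = 4,
                          pixel_size = 2, noise_sd = 0.02,
                          dim_px = c(64L, 64L)) {
  stopifnot(molecule_height > 0, tip_sigma >= 0, pixel_size > 0,
            noise_sd >= 0)
  margin <- 3 * tip_sigma + 2 * pixel_size
  if (is.null(trace)) {
    nr <- dim_px[1]; nc <- dim_px[2]
    mask <- matrix(FALSE, nr, nc)
  } else {
    stopifnot(inherits(trace, "backbone_trace"))
    p <- resample_trace(trace, pixel_size / 2)$points
    x <- p[, 1] - min(p[, 1]) + margin
    y <- p[, 2] - min(p[, 2]) + margin
    nc <- ceiling((max(x) + margin) / pixel_size)
    nr <- ceiling((max(y) + margin) / pixel_size)
    mask <- matrix(FALSE, nr, nc)
    rows <- pmin(pmax(floor(y / pixel_size) + 1L, 1L), nr)
    cols <- pmin(pmax(floor(x / pixel_size) + 1L, 1L), nc)
    mask[cbind(rows, cols)] <- TRUE
  }
  heights <- mask * molecule_height
  injected <- sum(mask) * molecule_height * pixel_size^2
  heights <- gaussian_blur(heights, tip_sigma / pixel_size)
  if (noise_sd > 0) {
    heights <- heights +
      with_seed(seed, matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc))
  }
  afm_image(heights, pixel_size, background = 0,
            meta = list(truth = list(injected_volume = injected,
                                     molecule_height = molecule_height,
                                     tip_sigma = tip_sigma,
                                     noise_sd = noise_sd, seed = seed)))
}

#' Generate a synthetic rate series
#'
#' Forward-evaluates the bimolecular (`k = c*k_on + k_off`), two-step
#' (`k = c*k_b*k_c / (c*k_b + k_c)`) or Bell (`k = k0*exp(F*dx/kBT)`) model
#' on an abscissa grid and applies multiplicative log-normal noise (rates
#' are positive and fit on a log or relative scale). The reported
#' uncertainties are `rate * noise_sd`.
#'
#' @param model `"bimolecular"`, `"two_step"` or `"bell"`.
#' @param true_params Named list: `k_on`, `k_off` for bimolecular; `k_b`,
#'   `k_c` for two-step; `k0`, `delta_x` for Bell.
#' @param abscissa Concentrations (nM) or forces (pN), positive.
#' @param seed Integer seed (required).
#' @param noise_sd SD of the log-normal noise (sdlog). Default 0.
#' @param constants A [sm_constants()] object (Bell model only).
#'
#' @return A [rate_series()] with ground truth attached as attribute
#'   `truth`.
#' @export
gen_rate_series <- function(model = c("bimolecular", "two_step", "bell"),
                            true_params, abscissa, seed, noise_sd = 0,
                            constants = sm_constants()) {
  model <- match.arg(model)
  stopifnot(all(abscissa > 0), noise_sd >= 0)
  k <- switch(model,
    bimolecular = abscissa * true_params$k_on + true_params$k_off,
    two_step = two_step_rate(abscissa, true_params$k_b, true_params$k_c),
    bell = bell_rate(abscissa, true_params$k0, true_params$delta_x,
                     constants))
  if (any(k <= 0)) stop_domain("generated rates must be positive")
  if (noise_sd > 0) {
    k <- k * exp(with_seed(seed, stats::rnorm(length(k), 0, noise_sd)))
  }
  out <- rate_series(abscissa, k,
                     uncertainties = if (noise_sd > 0) k * noise_sd else NULL)
  attr(out, "truth") <- c(list(model = model, noise_sd = noise_sd,
                               seed = seed), true_params)
  out
}
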