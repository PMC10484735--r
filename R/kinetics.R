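#' Constant-force time-extension trace
#'
#' Extension vs time of a tethered molecule held at fixed force and fixed
#' free-protein concentration; the object of kinetic decomposition.
#'
#' @param time Times in s, strictly increasing.
#' @param extension Extensions in nm, same length.
#' @param force Applied tension in pN (>= 0), or `NA`.
#' @param concentration Free-protein concentration in nM (>= 0), or `NA`.
#' @param phase `"binding"` or `"dissociation"`.
#' @param meta Named list of metadata (generator ground truth etc.).
#'
#' @return An object of class `tet`.
#' @export
time_extension_trace <- function(time, extension, force = NA_real_,
                                 concentration = NA_real_,
                                 phase = c("binding", "dissociation"),
                                 meta = list()) {
  phase <- match.arg(phase)
  time <- as.numeric(time)
  extension <- as.numeric(extension)
  if (length(time) != length(extension)) {
    stop_domain("time and extension must have equal length")
  }
  if (any(!is.finite(time)) || any(!is.finite(extension))) {
    stop_domain("time and extension must be finite")
  }
  if (any(diff(time) <= 0)) stop_domain("time must be strictly increasing")
  if (!is.na(force) && force < 0) stop_domain("force must be >= 0")
  if (!is.na(concentration) && concentration < 0) {
    stop_domain("concentration must be >= 0")
  }
  structure(list(time = time, extension = extension, force = force,
                 concentration = concentration, phase = phase, meta = meta),
            class = "tet")
}

#' @export
print.tet <- function(x, ...) {
  cat(sprintf("time-extension trace (%s): %d samples over %.3g s, F = %s pN, c = %s nM\n",
              x$phase, length(x$time), diff(range(x$time)),
              format(x$force), format(x$concentration)))
  invisible(x)
}

## Extract (t, x) from a tet or a plain list(time, extension).
trace_tx <- function(trace) {
  if (inherits(trace, "tet")) list(t = trace$time, x = trace$extension)
  else list(t = trace$time, x = trace$extension)
}

#' Fit a sum of saturating/decaying exponentials to a trace
#'
#' Least-squares fit of `x(t) = x_eq - sum_i A_i exp(-k_i t)` with one or two
#' rates. Amplitudes are signed: positive amplitudes describe an approach to
#' the plateau from below (elongation), negative from above (compaction).
#' Rates are returned in descending order. For `n_rates = 2`, a rate
#' separation below 1.5x is considered unresolved and the fit falls back to
#' a single rate with `fallback = TRUE`.
#'
#' @param trace A [time_extension_trace()] (or list with `time`, `extension`).
#' @param n_rates 1 or 2.
#'
#' @return A list of class `exp_fit`: `x_eq`, `amplitudes`, `rates` (s^-1,
#'   descending), their standard errors, `rss`, `n`, `n_rates`, `fallback`.
#' @export
fit_exponential <- function(trace, n_rates = 1) {
  stopifnot(n_rates %in% c(1, 2))
  d <- trace_tx(trace)
  t <- d$t - d$t[1]
  x <- d$x
  n <- length(t)
  if (n < 4 * n_rates + 2) {
    stop_insufficient(sprintf("trace too short for a %d-rate fit (%d samples)",
                              n_rates, n))
  }

  if (diff(range(x)) == 0) {
    return(structure(list(x_eq = x[1], amplitudes = rep(0, n_rates),
                          rates = rep(NA_real_, n_rates),
                          se = list(x_eq = 0, amplitudes = rep(0, n_rates),
                                    rates = rep(NA_real_, n_rates)),
                          rss = 0, n = n, n_rates = n_rates,
                          fallback = FALSE),
                     class = "exp_fit"))
  }

  ntail <- max(3L, ceiling(0.1 * n))
  xeq0 <- mean(x[(n - ntail + 1L):n])
  A0 <- xeq0 - x[1]
  ## crude rate scale from time-to-half-amplitude
  ih <- which(abs(x - x[1]) >= abs(A0) / 2)
  k0 <- if (length(ih) && t[ih[1]] > 0) log(2) / t[ih[1]] else 3 / max(t)
  k0 <- min(max(k0, 1e-6), 1e4)

  ctrl <- stats::nls.control(maxiter = 500, warnOnly = FALSE)
  fit1 <- function() {
    stats::nls(x ~ xeq - A * exp(-k * tt),
               data = list(x = x, tt = t),
               start = list(xeq = xeq0, A = A0, k = k0),
               algorithm = "port",
               lower = c(-Inf, -Inf, 1e-8), upper = c(Inf, Inf, 1e6),
               control = ctrl)
  }

  pack <- function(fit, n_rates, fallback) {
    cf <- stats::coef(fit)
    se <- nls_se(fit)
    if (n_rates == 1) {
      amps <- cf[["A"]]; rates <- cf[["k"]]
      amp_se <- unname(se["A"]); rate_se <- unname(se["k"])
    } else {
      ord <- order(c(cf[["k1"]], cf[["k2"]]), decreasing = TRUE)
      amps <- c(cf[["A1"]], cf[["A2"]])[ord]
      rates <- c(cf[["k1"]], cf[["k2"]])[ord]
      amp_se <- unname(c(se["A1"], se["A2"])[ord])
      rate_se <- unname(c(se["k1"], se["k2"])[ord])
    }
    res <- stats::resid(fit)
    structure(list(x_eq = cf[["xeq"]], amplitudes = unname(amps),
                   rates = unname(rates),
                   se = list(x_eq = unname(se["xeq"]), amplitudes = amp_se,
                             rates = rate_se),
                   rss = sum(res^2), n = n, n_rates = n_rates,
                   fallback = fallback),
              class = "exp_fit")
  }

  if (n_rates == 1) {
    fit <- tryCatch(fit1(), error = function(e)
      stop_fit_failure(paste("single-exponential fit failed:",
                             conditionMessage(e))))
    return(pack(fit, 1L, FALSE))
  }

  ## two rates: seed from the single-rate fit
  f1 <- tryCatch(fit1(), error = function(e) NULL)
  if (!is.null(f1)) {
    cf1 <- stats::coef(f1)
    kc <- cf1[["k"]]; Ac <- cf1[["A"]]; xc <- cf1[["xeq"]]
  } else {
    kc <- k0; Ac <- A0; xc <- xeq0
  }
  fit2 <- tryCatch(
    stats::nls(x ~ xeq - A1 * exp(-k1 * tt) - A2 * exp(-k2 * tt),
               data = list(x = x, tt = t),
               start = list(xeq = xc, A1 = Ac / 2, A2 = Ac / 2,
                            k1 = kc * 5, k2 = kc / 5),
               algorithm = "port",
               lower = c(-Inf, -Inf, -Inf, 1e-8, 1e-8),
               upper = c(Inf, Inf, Inf, 1e6, 1e6),
               control = ctrl),
    error = function(e) NULL)

  if (is.null(fit2)) {
    if (is.null(f1)) stop_fit_failure("two-rate exponential fit failed")
    return(pack(f1, 1L, TRUE))
  }
  cf2 <- stats::coef(fit2)
  ks <- sort(c(cf2[["k1"]], cf2[["k2"]]), decreasing = TRUE)
  if (ks[2] <= 0 || ks[1] / ks[2] < 1.5) {
    if (is.null(f1)) f1 <- fit1()
    return(pack(f1, 1L, TRUE))
  }
  pack(fit2, 2L, FALSE)
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%d-rate exponential fit%s: x_eq = %.4g nm\n", x$n_rates,
              if (x$fallback) " (fallback from 2 rates)" else "", x$x_eq))
  for (i in seq_len(x$n_rates)) {
    cat(sprintf("  A%d = %.4g nm, k%d = %.4g s^-1\n", i, x$amplitudes[i],
                i, x$rates[i]))
  }
  invisible(x)
}

## Global refinement of the full three-phase binding model; returns NULL on
## failure so the caller keeps the segment estimates.
refine_binding_fit <- function(t, x, x0, d1, k1, d2, k2, d3, k3) {
  fit <- tryCatch(
    stats::nls(x ~ X0 - D1 * (1 - exp(-K1 * tt)) + D2 * (1 - exp(-K2 * tt)) +
                 D3 * (1 - exp(-K3 * tt)),
               data = list(x = x, tt = t),
               start = list(X0 = x0, D1 = d1, K1 = k1, D2 = d2, K2 = k2,
                            D3 = d3, K3 = k3),
               algorithm = "port",
               lower = c(-Inf, 0, 1e-8, 0, 1e-8, 0, 1e-8),
               upper = c(Inf, Inf, 1e6, Inf, 1e6, Inf, 1e6),
               control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(x0 = cf[["X0"]], d1 = cf[["D1"]], k1 = cf[["K1"]], d2 = cf[["D2"]],
       k2 = cf[["K2"]], d3 = cf[["D3"]], k3 = cf[["K3"]],
       rss = sum(stats::resid(fit)^2), se = nls_se(fit))
}

#' Decompose a constant-force binding trace into sequential phases
#'
#' Cooperative SSB binding at constant force produces up to three sequential
#' phases of ssDNA extension change: a fast initial compaction (amplitude
#' `dx1` < 0, rate `k1`) followed by two kinetically distinct elongations
#' (`dx2`, `k2` and `dx3`, `k3`). The decomposition
#' (i) smooths the trace with a centered moving average spanning
#' `smooth_window` seconds, (ii) estimates the noise SD from the
#' first-difference MAD, (iii) locates the global extension minimum of the
#' smoothed trace; if the minimum lies more than `min_depth_sd` noise SDs
#' below both endpoints the trace is split there: a single-exponential
#' approach is fit before the minimum (compaction phase) and a two-rate
#' decaying exponential after it (elongation phases), and the full
#' three-phase model is then refined globally from those starting values.
#' (iv) Otherwise the trace is classified as monotonic and one- and two-rate
#' exponential fits are compared by a residual F-test at `alpha`; phases
#' whose fitted amplitude does not exceed `min_depth_sd` noise SDs are
#' reported as absent with zero amplitude.
#'
#' @param trace A [time_extension_trace()] with `phase = "binding"`.
#' @param smooth_window Smoothing window in seconds. Default 1.
#' @param min_depth_sd Minimum-depth / phase-presence criterion in units of
#'   the noise SD. Default 3.
#' @param alpha Significance level of the F-test used for one- vs two-rate
#'   model selection on monotonic traces. Default 0.05.
#'
#' @return A list of class `binding_decomposition` with `dx1` (<= 0), `dx2`,
#'   `dx3` (>= 0), rates `k1`, `k2`, `k3` (NA where a phase is absent),
#'   `x_init`, `x_eq`, logical `present_phases`, `noise_sd`, `structure`
#'   (`"triphasic"`, `"biphasic_elongation"`, `"monophasic_compaction"`,
#'   `"monophasic_elongation"` or `"constant"`), and `flags`.
#' @seealso [gen_binding_trace()], [fit_exponential()]
#' @export
decompose_binding_trace <- function(trace, smooth_window = 1,
                                    min_depth_sd = 3, alpha = 0.05) {
  d <- trace_tx(trace)
  t <- d$t - d$t[1]
  x <- d$x
  n <- length(t)
  if (n < 10) stop_insufficient("binding trace too short to decompose")
  dt <- stats::median(diff(t))
  w <- max(1L, round(smooth_window / dt))
  xs <- moving_average(x, w)
  sd_noise <- noise_sd_mad(x)
  thresh <- min_depth_sd * max(sd_noise, .Machine$double.eps)

  flags <- character(0)
  out <- list(dx1 = 0, dx2 = 0, dx3 = 0, k1 = NA_real_, k2 = NA_real_,
              k3 = NA_real_, x_init = x[1], x_eq = NA_real_,
              present_phases = c(phase1 = FALSE, phase2 = FALSE,
                                 phase3 = FALSE),
              noise_sd = sd_noise, structure = "constant", flags = flags)

  imin <- which.min(xs)
  interior <- imin > max(w, 3L) && imin < n - max(w, 3L)
  depth <- min(xs[1], xs[n]) - xs[imin]

  if (interior && depth > thresh) {
    ## triphasic: compaction to the minimum, then biphasic elongation
    pre <- list(time = t[1:imin], extension = x[1:imin])
    post <- list(time = t[imin:n] - t[imin], extension = x[imin:n])
    f_pre <- fit_exponential(pre, 1)
    f_post <- fit_exponential(post, 2)
    if (f_post$n_rates < 2) flags <- c(flags, "post_minimum_rate_collapse")

    d1 <- -f_pre$amplitudes[1]           # compaction amplitude, positive
    k1 <- f_pre$rates[1]
    if (f_post$n_rates == 2) {
      ## shift post-segment amplitudes back to t = 0 of the full trace
      d23 <- f_post$amplitudes
      k23 <- f_post$rates
      d2 <- min(d23[1] * exp(min(k23[1] * t[imin], 50)), 10 * abs(d1) + 1e4)
      d3 <- d23[2] * exp(min(k23[2] * t[imin], 50))
      k2 <- k23[1]; k3 <- k23[2]
    } else {
      d2 <- f_post$amplitudes[1]; k2 <- f_post$rates[1]
      d3 <- d2 / 2; k3 <- k2 / 10
    }
    ref <- refine_binding_fit(t, x, x[1], max(d1, 0), k1, max(d2, 0), k2,
                              max(d3, 0), k3)
    if (is.null(ref)) {
      flags <- c(flags, "global_refinement_failed")
      ref <- list(x0 = x[1], d1 = d1, k1 = k1, d2 = d2, k2 = k2,
                  d3 = if (f_post$n_rates == 2) d3 else 0,
                  k3 = if (f_post$n_rates == 2) k3 else NA_real_)
    }
    out$dx1 <- -ref$d1; out$k1 <- ref$k1
    out$dx2 <- ref$d2;  out$k2 <- ref$k2
    out$dx3 <- ref$d3;  out$k3 <- ref$k3
    out$x_init <- ref$x0
    out$x_eq <- ref$x0 - ref$d1 + ref$d2 + ref$d3
    out$present_phases <- c(phase1 = abs(out$dx1) > thresh,
                            phase2 = out$dx2 > thresh,
                            phase3 = out$dx3 > thresh)
    out$structure <- "triphasic"
  } else {
    ## monotonic: one vs two rates by residual F-test
    f1 <- fit_exponential(trace, 1)
    if (all(f1$amplitudes == 0)) {
      out$x_eq <- f1$x_eq
      out$flags <- flags
      return(structure(out, class = "binding_decomposition"))
    }
    f2 <- tryCatch(fit_exponential(trace, 2), error = function(e) NULL)
    use2 <- FALSE
    if (!is.null(f2) && f2$n_rates == 2 && f2$rss < f1$rss) {
      Fstat <- ((f1$rss - f2$rss) / 2) / (f2$rss / (n - 5))
      pval <- stats::pf(Fstat, 2, n - 5, lower.tail = FALSE)
      resolvable <- all(abs(f2$amplitudes) > thresh)
      use2 <- pval < alpha && resolvable
    }
    if (use2) {
      amps <- f2$amplitudes; ks <- f2$rates
      neg <- amps < 0
      if (any(neg)) {
        ## mixed compaction + elongation without an interior minimum
        i1 <- which(neg)[1]
        out$dx1 <- amps[i1]; out$k1 <- ks[i1]
        ipos <- which(!neg)
        if (length(ipos)) {
          out$dx3 <- amps[ipos[1]]; out$k3 <- ks[ipos[1]]
        }
        out$structure <- "biphasic_mixed"
      } else {
        out$dx2 <- amps[1]; out$k2 <- ks[1]
        out$dx3 <- amps[2]; out$k3 <- ks[2]
        out$structure <- "biphasic_elongation"
      }
      out$x_eq <- f2$x_eq
    } else {
      A <- f1$amplitudes[1]
      if (abs(A) <= thresh) {
        out$structure <- "constant"
        out$x_eq <- f1$x_eq
      } else if (A < 0) {
        out$dx1 <- A; out$k1 <- f1$rates[1]
        out$structure <- "monophasic_compaction"
        out$x_eq <- f1$x_eq
      } else {
        ## single elongation equilibrating to the plateau: the slow phase
        out$dx3 <- A; out$k3 <- f1$rates[1]
        out$structure <- "monophasic_elongation"
        out$x_eq <- f1$x_eq
      }
      if (!is.null(f2) && f2$fallback) flags <- c(flags, "rate_collapse_fallback")
    }
    out$present_phases <- c(phase1 = out$dx1 < 0, phase2 = out$dx2 > 0,
                            phase3 = out$dx3 > 0)
  }

  ## equilibration check: final 10% of samples should sit at the plateau
  ntail <- max(3L, ceiling(0.1 * n))
  tail_mean <- mean(x[(n - ntail + 1L):n])
  if (!is.na(out$x_eq) &&
      abs(tail_mean - out$x_eq) > max(3 * sd_noise / sqrt(ntail), 1e-12)) {
    flags <- c(flags, "non_equilibrated_plateau")
  }
  out$flags <- flags
  structure(out, class = "binding_decomposition")
}

#' @export
print.binding_decomposition <- function(x, ...) {
  cat(sprintf("binding decomposition (%s):\n", x$structure))
  cat(sprintf("  dx1 = %.4g nm (k1 = %.4g), dx2 = %.4g (k2 = %.4g), dx3 = %.4g (k3 = %.4g)\n",
              x$dx1, x$k1, x$dx2, x$k2, x$dx3, x$k3))
  cat(sprintf("  x: %.4g -> %.4g nm, noise sd %.3g nm\n",
              x$x_init, x$x_eq, x$noise_sd))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Decompose a dissociation trace into linear and exponential components
#'
#' Protein dissociation after free protein is removed produces extension
#' changes that are, depending on force and prior protein density, linear in
#' time (zeroth-order dissociation from cluster ends), a single decaying
#' exponential (noncooperative dissociation along the whole substrate), or
#' their sum. The three candidate models are fit by least squares and
#' compared by corrected AIC; among candidates within `delta_aicc` of the
#' best, the most parsimonious is returned, with an `ambiguous` flag if more
#' than one candidate was in that set. Exponential components whose fitted
#' rate is slower than `2 / duration` (indistinguishable from a line over
#' the observation window) or whose amplitude is below twice the noise SD
#' are treated as unsupported.
#'
#' @param trace A [time_extension_trace()] starting at buffer exchange
#'   (t = 0).
#' @param delta_aicc AICc margin within which models are considered
#'   equivalent. Default 2.
#'
#' @return A list of class `dissociation_decomposition`: `mode` (one of
#'   `"linear"`, `"linear_plus_exponential"`, `"exponential"`),
#'   `linear_slope` (nm/s, `NA` when absent), `exp_amplitude`, `exp_rate`
#'   (`NA` when absent), `intercept`, `slope_normalized` (slope divided by
#'   the magnitude of the total extension change, s^-1), `aicc` for all
#'   candidates, and `ambiguous`.
#' @seealso [gen_dissociation_trace()]
#' @export
decompose_dissociation_trace <- function(trace, delta_aicc = 2) {
  d <- trace_tx(trace)
  t <- d$t - d$t[1]
  x <- d$x
  n <- length(t)
  if (n < 8) stop_insufficient("dissociation trace too short to decompose")
  duration <- max(t)
  sd_noise <- noise_sd_mad(x)
  k_min <- 2 / duration
  ctrl <- stats::nls.control(maxiter = 500, warnOnly = FALSE)

  cand <- list()

  ## pure linear
  lin <- stats::lm(x ~ t)
  cand$linear <- list(rss = sum(stats::resid(lin)^2), k = 3,
                      slope = unname(stats::coef(lin)[2]),
                      intercept = unname(stats::coef(lin)[1]),
                      amp = NA_real_, rate = NA_real_)

  ## pure exponential x = xe - A exp(-k t)
  ntail <- max(3L, ceiling(0.1 * n))
  xe0 <- mean(x[(n - ntail + 1L):n])
  A0 <- xe0 - x[1]
  ih <- which(abs(x - x[1]) >= abs(A0) / 2)
  k0 <- if (length(ih) && t[ih[1]] > 0) log(2) / t[ih[1]] else 5 / duration
  fe <- tryCatch(
    stats::nls(x ~ xe - A * exp(-k * tt), data = list(x = x, tt = t),
               start = list(xe = xe0, A = A0, k = max(k0, k_min)),
               algorithm = "port", lower = c(-Inf, -Inf, 1e-8),
               upper = c(Inf, Inf, 1e6), control = ctrl),
    error = function(e) NULL)
  if (!is.null(fe)) {
    cf <- stats::coef(fe)
    if (cf[["k"]] >= k_min && abs(cf[["A"]]) >= 2 * sd_noise) {
      cand$exponential <- list(rss = sum(stats::resid(fe)^2), k = 4,
                               slope = NA_real_,
                               intercept = cf[["xe"]] - cf[["A"]],
                               amp = cf[["A"]], rate = cf[["k"]])
    }
  }

  ## linear + exponential x = a + b t - A exp(-k t)
  half <- t >= duration / 2
  late <- stats::lm(x[half] ~ t[half])
  b0 <- unname(stats::coef(late)[2])
  a0 <- unname(stats::coef(late)[1])
  A0 <- a0 - x[1]
  fle <- tryCatch(
    stats::nls(x ~ a + b * tt - A * exp(-k * tt), data = list(x = x, tt = t),
               start = list(a = a0, b = b0, A = A0,
                            k = max(5 / duration, k_min)),
               algorithm = "port", lower = c(-Inf, -Inf, -Inf, 1e-8),
               upper = c(Inf, Inf, Inf, 1e6), control = ctrl),
    error = function(e) NULL)
  if (!is.null(fle)) {
    cf <- stats::coef(fle)
    if (cf[["k"]] >= k_min && abs(cf[["A"]]) >= 2 * sd_noise) {
      cand$linear_plus_exponential <- list(
        rss = sum(stats::resid(fle)^2), k = 5,
        slope = cf[["b"]], intercept = cf[["a"]],
        amp = cf[["A"]], rate = cf[["k"]])
    }
  }

  ic <- vapply(cand, function(m) aicc(max(m$rss, 1e-300), n, m$k), numeric(1))
  best_ic <- min(ic)
  close <- names(ic)[ic - best_ic < delta_aicc]
  ## parsimony tie-break among statistically equivalent candidates
  npar <- vapply(cand[close], `[[`, numeric(1), "k")
  mode <- close[which.min(npar)]
  sel <- cand[[mode]]

  total <- abs(x[n] - x[1])
  structure(list(
    mode = mode,
    linear_slope = sel$slope,
    exp_amplitude = sel$amp,
    exp_rate = sel$rate,
    intercept = sel$intercept,
    slope_normalized = if (!is.na(sel$slope) && total > 0)
      sel$slope / total else NA_real_,
    noise_sd = sd_noise,
    aicc = ic,
    ambiguous = length(close) > 1
  ), class = "dissociation_decomposition")
}

#' @export
print.dissociation_decomposition <- function(x, ...) {
  cat(sprintf("dissociation decomposition: mode = %s%s\n", x$mode,
              if (x$ambiguous) " (ambiguous)" else ""))
  if (!is.na(x$linear_slope)) {
    cat(sprintf("  slope = %.4g nm/s (normalized %.4g s^-1)\n",
                x$linear_slope, x$slope_normalized))
  }
  if (!is.na(x$exp_rate)) {
    cat(sprintf("  exponential: A = %.4g nm, k = %.4g s^-1\n",
                x$exp_amplitude, x$exp_rate))
  }
  invisible(x)
}

#' Series of rates vs force or concentration
#'
#' @param abscissa Forces (pN) or concentrations (nM).
#' @param rates Observed rates in s^-1, > 0.
#' @param uncertainties Optional rate uncertainties (SEM), same length.
#'
#' @return An object of class `rate_series`.
#' @export
rate_series <- function(abscissa, rates, uncertainties = NULL) {
  abscissa <- as.numeric(abscissa)
  rates <- as.numeric(rates)
  if (length(abscissa) != length(rates)) {
    stop_domain("abscissa and rates must have equal length")
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop_domain("rates must be finite and positive")
  }
  if (!is.null(uncertainties) && length(uncertainties) != length(rates)) {
    stop_domain("uncertainties must match rates in length")
  }
  structure(list(abscissa = abscissa, rates = rates,
                 uncertainties = uncertainties), class = "rate_series")
}

#' Fit the Bell model to force-dependent rates
#'
#' The Bell model `k(F) = k0 * exp(F * dx / kBT)` relates a rate to the
#' applied force through a signed transition-state length `dx`. The fit is a
#' (weighted) linear regression of `ln k` on force: `dx = slope * kBT`,
#' `k0 = exp(intercept)`. When rate uncertainties are present the points are
#' weighted by `(k / sigma)^2`, the inverse variance of `ln k`.
#'
#' @param series A [rate_series()] with force (pN) abscissa, >= 3 points.
#' @param constants A [sm_constants()] object.
#'
#' @return A list of class `bell_fit`: `k0` (s^-1), `delta_x` (nm, signed),
#'   `k0_se`, `delta_x_se`, `n`.
#' @export
fit_bell <- function(series, constants = sm_constants()) {
  stopifnot(inherits(series, "rate_series"))
  if (length(series$rates) < 3) {
    stop_insufficient("Bell fit needs at least 3 force points")
  }
  F <- series$abscissa
  y <- log(series$rates)
  w <- if (!is.null(series$uncertainties)) {
    (series$rates / series$uncertainties)^2
  } else NULL
  fit <- stats::lm(y ~ F, weights = w)
  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(
    k0 = exp(unname(cf[1])),
    delta_x = unname(cf[2]) * constants$kBT,
    k0_se = exp(unname(cf[1])) * unname(se[1]),
    delta_x_se = unname(se[2]) * constants$kBT,
    n = length(F)
  ), class = "bell_fit")
}

#' @export
print.bell_fit <- function(x, ...) {
  cat(sprintf("Bell fit: k0 = %.4g s^-1, delta_x = %.4g +/- %.2g nm (n = %d)\n",
              x$k0, x$delta_x, x$delta_x_se, x$n))
  invisible(x)
}

#' Predicted Bell-model rate
#'
#' @param force Force(s) in pN.
#' @param k0 Zero-force rate in s^-1.
#' @param delta_x Signed transition-state length in nm.
#' @param constants A [sm_constants()] object.
#' @return Rate(s) in s^-1.
#' @export
bell_rate <- function(force, k0, delta_x, constants = sm_constants()) {
  k0 * exp(force * delta_x / constants$kBT)
}

#' Fit the bimolecular binding model to concentration-dependent rates
#'
#' For simple on-off binding the observed equilibration rate is
#' `k_obs = c * k_on + k_off`; a (weighted) linear regression yields the
#' concentration-independent bimolecular on-rate (slope), the off-rate
#' (intercept) and the dissociation constant `K_D = k_off / k_on`.
#'
#' @param series A [rate_series()] with concentration (nM) abscissa,
#'   >= 2 points. Points are weighted by inverse variance when
#'   uncertainties are present.
#'
#' @return A list of class `bimolecular_fit`: `k_on` (nM^-1 s^-1), `k_off`
#'   (s^-1), `K_D` (nM), standard errors, `n`, and `flag_nonpositive` when
#'   a fitted rate is not positive (extrapolation unreliable).
#' @export
fit_bimolecular <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  if (length(series$rates) < 2) {
    stop_insufficient("bimolecular fit needs at least 2 concentrations")
  }
  cc <- series$abscissa
  y <- series$rates
  w <- if (!is.null(series$uncertainties)) 1 / series$uncertainties^2 else NULL
  fit <- stats::lm(y ~ cc, weights = w)
  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) c(NA_real_, NA_real_))
  k_on <- unname(cf[2]); k_off <- unname(cf[1])
  structure(list(
    k_on = k_on, k_off = k_off,
    K_D = if (k_on != 0) k_off / k_on else NA_real_,
    k_on_se = unname(se[2]), k_off_se = unname(se[1]),
    n = length(cc),
    flag_nonpositive = (k_on <= 0) || (k_off < 0)
  ), class = "bimolecular_fit")
}

#' @export
print.bimolecular_fit <- function(x, ...) {
  cat(sprintf("bimolecular fit: k_on = %.4g nM^-1 s^-1, k_off = %.4g s^-1, K_D = %.4g nM\n",
              x$k_on, x$k_off, x$K_D))
  if (x$flag_nonpositive) cat("  warning: non-positive fitted rate\n")
  invisible(x)
}

#' Two-step reaction model for the initial compaction rate
#'
#' The steady-state sequential two-step scheme
#' `k(c) = c * k_b * k_c / (c * k_b + k_c)` describes a rate that increases
#' linearly with concentration (slope `k_b`, the diffusion-limited
#' bimolecular binding rate) before approaching the asymptote `k_c` (the
#' rate of the subsequent unimolecular compaction/oligomerization step).
#' Deconvolves the two rates by least squares.
#'
#' @param series A [rate_series()] with concentration (nM) abscissa,
#'   >= 3 points spanning the linear and asymptotic regimes. Weighted by
#'   inverse variance when uncertainties are present.
#'
#' @return A list of class `two_step_fit`: `k_b` (nM^-1 s^-1), `k_c`
#'   (s^-1), standard errors, `n`, and `flag_kc_unbounded` when the data do
#'   not leave the linear regime.
#' @export
fit_two_step <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  if (length(series$rates) < 3) {
    stop_insufficient("two-step fit needs at least 3 concentrations")
  }
  cc <- series$abscissa
  y <- series$rates
  w <- if (!is.null(series$uncertainties)) 1 / series$uncertainties^2 else NULL
  i1 <- which.min(cc)
  kb0 <- y[i1] / cc[i1]
  kc0 <- 1.5 * max(y)
  kc_cap <- 1e6 * max(y)
  dat <- list(y = y, cc = cc)
  fit <- tryCatch({
    if (is.null(w)) {
      stats::nls(y ~ cc * kb * kc / (cc * kb + kc), data = dat,
                 start = list(kb = kb0, kc = kc0), algorithm = "port",
                 lower = c(1e-12, 1e-12), upper = c(Inf, kc_cap),
                 control = stats::nls.control(maxiter = 500))
    } else {
      stats::nls(y ~ cc * kb * kc / (cc * kb + kc), data = dat,
                 weights = w,
                 start = list(kb = kb0, kc = kc0), algorithm = "port",
                 lower = c(1e-12, 1e-12), upper = c(Inf, kc_cap),
                 control = stats::nls.control(maxiter = 500))
    }
  }, error = function(e) {
    stop_fit_failure(paste("two-step fit failed:", conditionMessage(e)))
  })
  cf <- stats::coef(fit)
  se <- nls_se(fit)
  kc <- cf[["kc"]]
  unbounded <- kc >= 0.99 * kc_cap ||
    (is.finite(se["kc"]) && se["kc"] > kc)
  structure(list(
    k_b = cf[["kb"]], k_c = kc,
    k_b_se = unname(se["kb"]), k_c_se = unname(se["kc"]),
    n = length(cc),
    flag_kc_unbounded = unname(unbounded)
  ), class = "two_step_fit")
}

#' @export
print.two_step_fit <- function(x, ...) {
  cat(sprintf("two-step fit: k_b = %.4g nM^-1 s^-1, k_c = %.4g s^-1%s\n",
              x$k_b, x$k_c,
              if (x$flag_kc_unbounded) " (k_c unbounded: linear regime)" else ""))
  invisible(x)
}

#' Predicted two-step rate
#'
#' @param concentration Concentration(s) in nM.
#' @param k_b Bimolecular binding rate in nM^-1 s^-1.
#' @param k_c Compaction/oligomerization rate in s^-1.
#' @return Rate(s) in s^-1.
#' @export
two_step_rate <- function(concentration, k_b, k_c) {
  concentration * k_b * k_c / (concentration * k_b + k_c)
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param k_off Off-rate in s^-1, >= 0.
#' @param k_on On-rate in nM^-1 s^-1, > 0.
#' @return `K_D = k_off / k_on` in nM.
#' @examples
#' compute_kd(0.11, 0.0024) # ~46 nM
#' @export
compute_kd <- function(k_off, k_on) {
  if (!is.finite(k_on) || k_on <= 0) stop_domain("k_on must be positive")
  if (!is.finite(k_off) || k_off < 0) stop_domain("k_off must be >= 0")
  k_off / k_on
}
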