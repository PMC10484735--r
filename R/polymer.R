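#' Polymer parameters for FJC/WLC elasticity models
#'
#' Container for the mechanical parameters of a single tethered molecule:
#' contour length per nucleotide, substrate length in nucleotides,
#' persistence length, and (optionally) an enthalpic stretch modulus. The
#' total contour length is `contour_per_nt * n_nt`. An infinite
#' `stretch_modulus` denotes the inextensible model, which is the default
#' throughout: at the low forces where these fits are performed (below 5-10
#' pN) enthalpic backbone stretching is negligible.
#'
#' @param contour_per_nt Contour length per nucleotide (nm/nt), > 0.
#' @param n_nt Substrate length in nucleotides, >= 1.
#' @param persistence Persistence length p in nm, > 0. For the FJC the Kuhn
#'   length is taken as b = 2p so that FJC and WLC persistence lengths are
#'   directly comparable.
#' @param stretch_modulus Elastic stretch modulus S in pN; `Inf` (default)
#'   selects the inextensible model.
#'
#' @return An object of class `polymer_params`.
#' @examples
#' polymer_params(0.56, 8100, 0.75)
#' @export
polymer_params <- function(contour_per_nt, n_nt, persistence,
                           stretch_modulus = Inf) {
  if (!is.finite(contour_per_nt) || contour_per_nt <= 0) {
    stop_domain("contour_per_nt must be positive")
  }
  if (!is.finite(n_nt) || n_nt < 1) stop_domain("n_nt must be >= 1")
  if (!is.finite(persistence) || persistence <= 0) {
    stop_domain("persistence must be positive")
  }
  if (is.na(stretch_modulus) || stretch_modulus <= 0) {
    stop_domain("stretch_modulus must be positive (Inf for inextensible)")
  }
  structure(list(contour_per_nt = contour_per_nt, n_nt = n_nt,
                 persistence = persistence,
                 stretch_modulus = stretch_modulus),
            class = "polymer_params")
}

#' @export
print.polymer_params <- function(x, ...) {
  cat(sprintf("polymer parameters: %.4g nm/nt x %d nt (L = %.4g nm), p = %.4g nm%s\n",
              x$contour_per_nt, round(x$n_nt),
              x$contour_per_nt * x$n_nt, x$persistence,
              if (is.finite(x$stretch_modulus))
                sprintf(", S = %.4g pN", x$stretch_modulus) else ""))
  invisible(x)
}

#' Force-extension curve of a tethered molecule
#'
#' The raw object of all polymer fits: paired force (pN) and end-to-end
#' extension (nm) samples recorded while a molecule is slowly stretched or
#' released, with optional metadata (substrate identity and length, protein,
#' free-protein concentration, generator ground truth).
#'
#' @param force Forces in pN (>= 0, finite).
#' @param extension Extensions in nm (finite), same length as `force`.
#' @param direction `"stretch"` or `"release"`.
#' @param meta Named list of metadata.
#'
#' @return An object of class `fec`.
#' @export
force_extension_curve <- function(force, extension,
                                  direction = c("stretch", "release"),
                                  meta = list()) {
  direction <- match.arg(direction)
  force <- as.numeric(force)
  extension <- as.numeric(extension)
  if (length(force) != length(extension)) {
    stop_domain("force and extension must have equal length")
  }
  if (any(!is.finite(force)) || any(!is.finite(extension))) {
    stop_domain("force and extension must be finite")
  }
  if (any(force < 0)) stop_domain("forces must be >= 0")
  structure(list(force = force, extension = extension, direction = direction,
                 meta = meta), class = "fec")
}

#' @export
print.fec <- function(x, ...) {
  cat(sprintf("force-extension curve (%s): %d samples, %.3g-%.3g pN\n",
              x$direction, length(x$force), min(x$force), max(x$force)))
  invisible(x)
}

## coth(u) - 1/u, the Langevin function, with a series expansion near zero
## to avoid catastrophic cancellation.
langevin <- function(u) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-4
  out[small] <- u[small] / 3 - u[small]^3 / 45
  ub <- u[!small]
  out[!small] <- 1 / tanh(ub) - 1 / ub
  out
}

#' Freely jointed chain extension at a given force
#'
#' Extension of a freely jointed chain with Kuhn length b = 2p:
#' `x(F) = Lc * (coth(Fb/kBT) - kBT/(Fb)) * (1 + F/S)`, where
#' `Lc = contour_per_nt * n_nt` is the total contour length. The enthalpic
#' factor `(1 + F/S)` is dropped for the inextensible model
#' (`stretch_modulus = Inf`). The F = 0 limit is evaluated explicitly as 0;
#' negative forces are a domain error.
#'
#' @param force Force(s) in pN, >= 0.
#' @param params A [polymer_params()] object.
#' @param constants A [sm_constants()] object.
#'
#' @return Extension(s) in nm.
#' @examples
#' p <- polymer_params(0.510, 8100, 1.9)
#' fjc_extension(c(1, 5, 10), p)
#' @export
fjc_extension <- function(force, params, constants = sm_constants()) {
  stopifnot(inherits(params, "polymer_params"))
  if (any(force < 0)) stop_domain("FJC extension is undefined for force < 0")
  Lc <- params$contour_per_nt * params$n_nt
  b <- 2 * params$persistence
  u <- force * b / constants$kBT
  x <- Lc * langevin(u)
  if (is.finite(params$stretch_modulus)) {
    x <- x * (1 + force / params$stretch_modulus)
  }
  x
}

## Marko-Siggia interpolation at relative extension z (internal scalar core).
ms_force <- function(z, persistence, kBT) {
  (kBT / persistence) * (1 / (4 * (1 - z)^2) - 1 / 4 + z)
}

#' Worm-like chain force at a given relative extension
#'
#' The inextensible Marko-Siggia interpolation formula
#' `F(z) = (kBT/p) * (1/(4(1-z)^2) - 1/4 + z)` with z = x/Lc the fractional
#' extension. The force diverges as z approaches 1, so `z >= 1` is a domain
#' error.
#'
#' @param relative_extension Fractional extension(s) z in `[0, 1)`.
#' @param params A [polymer_params()] object (only `persistence` is used).
#' @param constants A [sm_constants()] object.
#'
#' @return Force(s) in pN.
#' @examples
#' wlc_force(0.5, polymer_params(0.41, 8100, 20))
#' @export
wlc_force <- function(relative_extension, params,
                      constants = sm_constants()) {
  stopifnot(inherits(params, "polymer_params"))
  z <- relative_extension
  if (any(z < 0) || any(z >= 1)) {
    stop_domain("relative extension must lie in [0, 1): force diverges at z = 1")
  }
  ms_force(z, params$persistence, constants$kBT)
}

#' Worm-like chain extension at a given force
#'
#' Inverts the Marko-Siggia relation by bracketed root-finding on
#' z in `[0, 1 - 1e-12]` to a tolerance of 1e-10, followed by two Newton
#' polishing steps, and returns the absolute extension `z * Lc`.
#'
#' @inheritParams fjc_extension
#' @return Extension(s) in nm.
#' @export
wlc_extension <- function(force, params, constants = sm_constants()) {
  stopifnot(inherits(params, "polymer_params"))
  if (any(force < 0)) stop_domain("WLC extension is undefined for force < 0")
  Lc <- params$contour_per_nt * params$n_nt
  p <- params$persistence
  kBT <- constants$kBT
  z <- vapply(force, function(f) {
    if (f == 0) return(0)
    root <- stats::uniroot(function(z) ms_force(z, p, kBT) - f,
                           interval = c(0, 1 - 1e-12), tol = 1e-12)$root
    ## Newton polish: dF/dz = (kBT/p) * (1/(2(1-z)^3) + 1)
    for (i in 1:2) {
      g <- ms_force(root, p, kBT) - f
      dg <- (kBT / p) * (1 / (2 * (1 - root)^3) + 1)
      step <- g / dg
      cand <- root - step
      if (cand > 0 && cand < 1) root <- cand
    }
    root
  }, numeric(1))
  z * Lc
}

## Shared least-squares backend for the two polymer fits.
fit_polymer <- function(fec, model, f_max, n_nt, extensible, constants) {
  stopifnot(inherits(fec, "fec"))
  n_nt <- n_nt %||% fec$meta$n_nt
  if (is.null(n_nt)) {
    stop_domain("substrate length n_nt must be supplied (argument or fec meta)")
  }
  sel <- fec$force > 0 & fec$force <= f_max
  if (sum(sel) < 5) {
    stop_insufficient(sprintf(
      "insufficient data: %d samples with 0 < force <= %g pN (need >= 5)",
      sum(sel), f_max))
  }
  d <- data.frame(F = fec$force[sel], x = fec$extension[sel])

  fwd <- switch(model, FJC = fjc_extension, WLC = wlc_extension)
  pred <- function(F, cpn, p, S = Inf) {
    fwd(F, polymer_params(cpn, n_nt, p, S), constants)
  }

  cpn0 <- max(d$x) / n_nt
  p0 <- if (model == "FJC") 1 else 10
  ctrl <- stats::nls.control(maxiter = 500, warnOnly = FALSE)
  fit <- tryCatch({
    if (extensible) {
      stats::nls(x ~ pred(F, cpn, p, S), data = d,
                 start = list(cpn = cpn0, p = p0, S = 800),
                 algorithm = "port",
                 lower = c(1e-4, 1e-3, 1), control = ctrl)
    } else {
      stats::nls(x ~ pred(F, cpn, p), data = d,
                 start = list(cpn = cpn0, p = p0),
                 algorithm = "port",
                 lower = c(1e-4, 1e-3), control = ctrl)
    }
  }, error = function(e) {
    stop_fit_failure(sprintf("%s fit did not converge: %s (n = %d, window = (%g, %g] pN)",
                             model, conditionMessage(e), nrow(d), 0, f_max))
  })

  cf <- stats::coef(fit)
  se <- nls_se(fit)
  params <- polymer_params(cf[["cpn"]], n_nt, cf[["p"]],
                           if (extensible) cf[["S"]] else Inf)
  res <- d$x - stats::predict(fit)
  structure(list(
    model = model,
    params = params,
    param_uncertainties = c(contour_per_nt = unname(se["cpn"]),
                            persistence = unname(se["p"]),
                            stretch_modulus = if (extensible)
                              unname(se["S"]) else NA_real_),
    force_window = c(min(d$F), f_max),
    residual_rms = sqrt(mean(res^2)),
    n = nrow(d),
    fit = fit
  ), class = "polymer_fit")
}

#' @export
print.polymer_fit <- function(x, ...) {
  cat(sprintf("%s fit (window %.3g-%.3g pN, n = %d)\n", x$model,
              x$force_window[1], x$force_window[2], x$n))
  cat(sprintf("  contour: %.4g +/- %.2g nm/nt   persistence: %.4g +/- %.2g nm\n",
              x$params$contour_per_nt, x$param_uncertainties["contour_per_nt"],
              x$params$persistence, x$param_uncertainties["persistence"]))
  cat(sprintf("  residual rms: %.3g nm\n", x$residual_rms))
  invisible(x)
}

#' Fit the freely jointed chain model to a force-extension curve
#'
#' Least-squares fit of the (by default inextensible) FJC extension to all
#' samples with force in `(0, f_max]` pN, estimating the contour length per
#' nucleotide and the persistence length. This models substrates such as
#' bare ssDNA or ssDNA saturated with a noncooperatively binding protein,
#' where the chain remains freely jointed between rigid subunits. The fit
#' window defaults to 10 pN, below which the inextensible FJC describes the
#' data.
#'
#' @param fec A [force_extension_curve()].
#' @param f_max Upper force of the fit window in pN. Default 10.
#' @param n_nt Substrate length in nt; defaults to `fec$meta$n_nt`.
#' @param extensible If `TRUE`, also fit the stretch modulus S.
#' @param constants A [sm_constants()] object.
#'
#' @return An object of class `polymer_fit` with elements `model`, `params`
#'   ([polymer_params()]), `param_uncertainties`, `force_window`,
#'   `residual_rms`, `n` and the underlying `nls` fit.
#' @seealso [fit_wlc()], [gen_fec()]
#' @export
fit_fjc <- function(fec, f_max = 10, n_nt = NULL, extensible = FALSE,
                    constants = sm_constants()) {
  fit_polymer(fec, "FJC", f_max, n_nt, extensible, constants)
}

#' Fit the worm-like chain model to a force-extension curve
#'
#' Least-squares fit of the inextensible Marko-Siggia WLC to all samples
#' with force in `(0, f_max]` pN. This models cooperative protein-ssDNA
#' filaments, which behave as continuously flexible polymers. The fit window
#' defaults to 5 pN.
#'
#' @inheritParams fit_fjc
#' @param f_max Upper force of the fit window in pN. Default 5.
#' @return An object of class `polymer_fit`; see [fit_fjc()].
#' @export
fit_wlc <- function(fec, f_max = 5, n_nt = NULL, extensible = FALSE,
                    constants = sm_constants()) {
  fit_polymer(fec, "WLC", f_max, n_nt, extensible, constants)
}

#' Bin a force-extension curve by force
#'
#' Groups samples into left-closed force bins `[n*w, (n+1)*w)` pN keyed by
#' the integer lower edge, and reports the per-bin mean force, mean
#' extension, standard error of the mean extension, and sample count. Empty
#' bins are omitted. Singleton bins have `NA` SEM.
#'
#' @param fec A [force_extension_curve()].
#' @param bin_width Bin width in pN. Default 1.
#'
#' @return A data.frame with columns `bin` (lower edge, pN), `force_mean`,
#'   `extension_mean`, `extension_sem`, `n`.
#' @export
bin_fec <- function(fec, bin_width = 1) {
  stopifnot(inherits(fec, "fec"))
  if (length(fec$force) == 0) stop_domain("cannot bin an empty curve")
  if (bin_width <= 0) stop_domain("bin_width must be positive")
  key <- floor(fec$force / bin_width)
  agg <- lapply(split(seq_along(key), key), function(idx) {
    x <- fec$extension[idx]
    data.frame(bin = key[idx[1]] * bin_width,
               force_mean = mean(fec$force[idx]),
               extension_mean = mean(x),
               extension_sem = if (length(x) > 1)
                 stats::sd(x) / sqrt(length(x)) else NA_real_,
               n = length(x))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned extension change relative to a reference curve
#'
#' Bins both curves with [bin_fec()] and returns, for every force bin
#' present in both, the difference in mean extension
#' `dx = mean(complex) - mean(bare)` with the SEMs propagated in quadrature
#' (singleton-bin `NA` SEMs contribute zero). Used to compute the
#' equilibrium extension change of ssDNA caused by protein binding, as a
#' function of tension.
#'
#' @param fec_complex Curve of the protein-DNA complex.
#' @param fec_bare Curve of the bare substrate.
#' @param bin_width Bin width in pN. Default 1.
#'
#' @return A data.frame with columns `bin`, `force_mean` (mean of the two
#'   bin mean forces), `dx`, `dx_sem`, `n_complex`, `n_bare`.
#' @export
extension_change <- function(fec_complex, fec_bare, bin_width = 1) {
  bc <- bin_fec(fec_complex, bin_width)
  bb <- bin_fec(fec_bare, bin_width)
  m <- merge(bc, bb, by = "bin", suffixes = c("_complex", "_bare"))
  if (nrow(m) == 0) {
    stop_domain("curves share no force bin: cannot compute extension change")
  }
  s1 <- ifelse(is.na(m$extension_sem_complex), 0, m$extension_sem_complex)
  s2 <- ifelse(is.na(m$extension_sem_bare), 0, m$extension_sem_bare)
  out <- data.frame(
    bin = m$bin,
    force_mean = (m$force_mean_complex + m$force_mean_bare) / 2,
    dx = m$extension_mean_complex - m$extension_mean_bare,
    dx_sem = sqrt(s1^2 + s2^2),
    n_complex = m$n_complex,
    n_bare = m$n_bare
  )
  out[order(out$bin), , drop = FALSE]
}
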