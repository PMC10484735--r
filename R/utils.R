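# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
## state afterwards. All generators route their randomness through this so
## that a generator call never perturbs the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

## Centered moving average; ends use shrinking partial windows so the output
## has the same length as the input.
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  n <- length(x)
  y <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  half <- width %/% 2L
  for (i in which(is.na(y))) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    y[i] <- mean(x[lo:hi])
  }
  y
}

## Noise SD of a trace from the median absolute deviation of its first
## differences; insensitive to the slow deterministic component.
noise_sd_mad <- function(x) stats::mad(diff(x)) / sqrt(2)

## Corrected Akaike information criterion for a least-squares fit with
## k estimated parameters (error variance included by the caller).
aicc <- function(rss, n, k) {
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

## Standard errors from an nls fit, returned as a named vector; NA on failure.
nls_se <- function(fit) {
  out <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) NULL)
  if (is.null(out)) {
    cf <- stats::coef(fit)
    out <- stats::setNames(rep(NA_real_, length(cf)), names(cf))
  }
  out
}

stop_insufficient <- function(msg) {
  stop(errorCondition(msg, class = c("ssbfil_insufficient_data", "error")))
}

stop_fit_failure <- function(msg) {
  stop(errorCondition(msg, class = c("ssbfil_fit_failure", "error")))
}

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("ssbfil_domain_error", "error")))
}
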