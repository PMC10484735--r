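#' Ordered backbone trace of a surface-deposited molecule
#'
#' @param x,y Ordered coordinates in nm (>= 3 points, consecutive points
#'   distinct).
#' @param molecule_id Identifier.
#' @param meta Named list of metadata.
#'
#' @return An object of class `backbone_trace` with a two-column `points`
#'   matrix.
#' @export
backbone_trace <- function(x, y, molecule_id = NA_character_, meta = list()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  if (length(x) < 3) stop_domain("a backbone trace needs at least 3 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_domain("trace coordinates must be finite")
  }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg == 0)) stop_domain("consecutive trace points must be distinct")
  new_backbone_trace(cbind(x = x, y = y), molecule_id, meta)
}

## internal constructor without validation (used for subtraces)
new_backbone_trace <- function(points, molecule_id = NA_character_,
                               meta = list()) {
  structure(list(points = points, molecule_id = molecule_id, meta = meta),
            class = "backbone_trace")
}

#' @export
print.backbone_trace <- function(x, ...) {
  cat(sprintf("backbone trace%s: %d points, contour %.4g nm\n",
              if (!is.na(x$molecule_id)) paste0(" [", x$molecule_id, "]") else "",
              nrow(x$points), trace_contour_length(x)))
  invisible(x)
}

#' Contour length of a backbone trace
#'
#' Sum of the consecutive segment lengths.
#'
#' @param trace A [backbone_trace()].
#' @return Contour length in nm.
#' @export
trace_contour_length <- function(trace) {
  stopifnot(inherits(trace, "backbone_trace"))
  p <- trace$points
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

#' Resample a backbone trace to a uniform arc-length step
#'
#' Linear interpolation along the cumulative arc length at multiples of
#' `step`, preserving the first point.
#'
#' @param trace A [backbone_trace()].
#' @param step Arc-length step in nm.
#' @return A resampled `backbone_trace`.
#' @export
resample_trace <- function(trace, step) {
  stopifnot(inherits(trace, "backbone_trace"), step > 0)
  p <- trace$points
  s <- c(0, cumsum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)))
  total <- s[length(s)]
  grid <- seq(0, total, by = step)
  if (length(grid) < 2) {
    stop_insufficient("trace shorter than one resample step")
  }
  xs <- stats::approx(s, p[, 1], xout = grid)$y
  ys <- stats::approx(s, p[, 2], xout = grid)$y
  new_backbone_trace(cbind(x = xs, y = ys), trace$molecule_id, trace$meta)
}

#' Tangent-orientation correlation profile of traced molecules
#'
#' Resamples each trace to a uniform arc step, computes the tangent angle of
#' every resampled segment, and for every arc-length separation
#' `L = k * resample_step` the mean cosine of the tangent angle difference.
#' Per-molecule means are averaged with equal weight per molecule
#' (`weighting = "molecule"`, the default) or pooled over all pairs
#' (`weighting = "pooled"`). Traces shorter than two resample steps are
#' skipped with a warning. For a two-dimensional worm-like chain the profile
#' decays as `exp(-L / 2p)`.
#'
#' @param traces A [backbone_trace()] or a list of them.
#' @param resample_step Arc step in nm. Default 5.
#' @param max_separation Largest separation in nm; defaults to the longest
#'   usable separation.
#' @param weighting `"molecule"` or `"pooled"`.
#'
#' @return A data.frame of class `tangent_correlation` with columns
#'   `separation` (nm), `mean_cos`, `sem` (across molecules; `NA` for pooled
#'   weighting with one molecule), `n_pairs`, `n_molecules`.
#' @export
tangent_correlation <- function(traces, resample_step = 5,
                                max_separation = NULL,
                                weighting = c("molecule", "pooled")) {
  weighting <- match.arg(weighting)
  if (inherits(traces, "backbone_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)

  per_mol <- list()
  for (tr in traces) {
    rs <- tryCatch(resample_trace(tr, resample_step), error = function(e) NULL)
    if (is.null(rs) || nrow(rs$points) < 3) {
      warning("skipping trace shorter than 2 resample steps")
      next
    }
    p <- rs$points
    ang <- atan2(diff(p[, 2]), diff(p[, 1]))
    nseg <- length(ang)
    kmax <- nseg - 1L
    if (!is.null(max_separation)) {
      kmax <- min(kmax, floor(max_separation / resample_step))
    }
    if (kmax < 1L) next
    mc <- vapply(seq_len(kmax), function(k) {
      mean(cos(ang[(1L + k):nseg] - ang[1L:(nseg - k)]))
    }, numeric(1))
    np <- nseg - seq_len(kmax)
    per_mol[[length(per_mol) + 1L]] <- list(mc = mc, np = np)
  }
  if (!length(per_mol)) stop_insufficient("no trace long enough to correlate")

  kmax_all <- max(vapply(per_mol, function(m) length(m$mc), integer(1)))
  sep <- seq_len(kmax_all) * resample_step
  rows <- lapply(seq_len(kmax_all), function(k) {
    vals <- unlist(lapply(per_mol, function(m)
      if (length(m$mc) >= k) m$mc[k] else NULL))
    ns <- unlist(lapply(per_mol, function(m)
      if (length(m$np) >= k) m$np[k] else NULL))
    mc <- if (weighting == "molecule") mean(vals) else
      sum(vals * ns) / sum(ns)
    data.frame(separation = sep[k],
               mean_cos = mc,
               sem = if (length(vals) > 1)
                 stats::sd(vals) / sqrt(length(vals)) else NA_real_,
               n_pairs = sum(ns),
               n_molecules = length(vals))
  })
  out <- rbind(data.frame(separation = 0, mean_cos = 1, sem = 0,
                          n_pairs = sum(vapply(per_mol, function(m)
                            m$np[1] + 1L, numeric(1))),
                          n_molecules = length(per_mol)),
               do.call(rbind, rows))
  class(out) <- c("tangent_correlation", "data.frame")
  out
}

#' Fit the 2D worm-like-chain persistence length to a correlation profile
#'
#' Single-parameter least-squares fit of `mean_cos = exp(-L / 2p)` over
#' separations in `(0, L_max]`. A profile that does not decay (all
#' `mean_cos` at 1 within numerical noise) is reported as unbounded with
#' `p = Inf`; a profile with fewer than 3 positive correlations in the
#' window is a fit failure (over-flexible or loop-dominated input).
#'
#' @param profile A [tangent_correlation()] data.frame.
#' @param L_max Upper separation of the fit window in nm; defaults to the
#'   largest separation present.
#'
#' @return A list of class `persistence_fit`: `p` (nm), `p_se`, `L_max`,
#'   `n`, `unbounded`.
#' @export
fit_persistence_2d <- function(profile, L_max = NULL) {
  stopifnot(inherits(profile, "data.frame"),
            all(c("separation", "mean_cos") %in% names(profile)))
  L_max <- L_max %||% max(profile$separation)
  sel <- profile$separation > 0 & profile$separation <= L_max
  d <- profile[sel, , drop = FALSE]
  pos <- d$mean_cos > 0
  if (sum(pos) < 3) {
    stop_fit_failure("fewer than 3 positive correlations below L_max: over-flexible or loop-dominated profile")
  }
  ## initial estimate from the log-linear decay
  slope <- stats::coef(stats::lm(log(d$mean_cos[pos]) ~ 0 + d$separation[pos]))[[1]]
  if (slope >= -1e-10) {
    return(structure(list(p = Inf, p_se = NA_real_, L_max = L_max,
                          n = nrow(d), unbounded = TRUE),
                     class = "persistence_fit"))
  }
  p0 <- -1 / (2 * slope)
  fit <- tryCatch(
    stats::nls(mean_cos ~ exp(-separation / (2 * p)), data = d,
               start = list(p = p0), algorithm = "port",
               lower = 1e-6, control = stats::nls.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ## fall back to the log-linear estimate
    return(structure(list(p = p0, p_se = NA_real_, L_max = L_max,
                          n = nrow(d), unbounded = FALSE),
                     class = "persistence_fit"))
  }
  se <- nls_se(fit)
  structure(list(p = stats::coef(fit)[["p"]], p_se = unname(se["p"]),
                 L_max = L_max, n = nrow(d), unbounded = FALSE),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  if (x$unbounded) {
    cat("2D WLC persistence fit: no measurable decay (p unbounded)\n")
  } else {
    cat(sprintf("2D WLC persistence fit: p = %.4g +/- %.2g nm (L_max = %g nm, n = %d)\n",
                x$p, x$p_se, x$L_max, x$n))
  }
  invisible(x)
}

#' Longest loop-free segment of a backbone trace
#'
#' Deposited molecules can preserve solution loops: self-contacts where the
#' strand crosses over itself, producing tangent anticorrelations that bias
#' persistence estimates. A self-contact is a pair of points closer than
#' `contact_radius` in space but separated by more than `4 * contact_radius`
#' along the arc. Returns the longest contiguous run of points not involved
#' in any contact (the whole trace when there is none).
#'
#' @param trace A [backbone_trace()].
#' @param contact_radius Contact radius in nm. Default 4 (about twice the
#'   measured filament radius).
#'
#' @return A `backbone_trace` subtrace.
#' @export
longest_loopfree_segment <- function(trace, contact_radius = 4) {
  stopifnot(inherits(trace, "backbone_trace"), contact_radius > 0)
  p <- trace$points
  n <- nrow(p)
  s <- c(0, cumsum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)))
  cr2 <- contact_radius^2
  min_arc <- 4 * contact_radius
  involved <- rep(FALSE, n)
  chunk <- 512L
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    dx <- outer(p[idx, 1], p[, 1], "-")
    dy <- outer(p[idx, 2], p[, 2], "-")
    hit <- (dx * dx + dy * dy <= cr2) &
      (abs(outer(s[idx], s, "-")) > min_arc)
    any_hit <- rowSums(hit) > 0
    involved[idx] <- involved[idx] | any_hit
    involved <- involved | (colSums(hit) > 0)
  }
  if (!any(involved)) return(trace)
  runs <- rle(!involved)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  free <- which(runs$values)
  if (!length(free)) {
    stop_fit_failure("no loop-free segment found")
  }
  best <- free[which.max(runs$lengths[free])]
  keep <- starts[best]:ends[best]
  new_backbone_trace(p[keep, , drop = FALSE], trace$molecule_id, trace$meta)
}

#' AFM height image
#'
#' @param heights Matrix of heights in nm (rows = y, columns = x).
#' @param pixel_size Pixel edge in nm, > 0.
#' @param background Known background level in nm, or `NA` to estimate.
#' @param meta Named list of metadata.
#'
#' @return An object of class `afm_image`.
#' @export
afm_image <- function(heights, pixel_size, background = NA_real_,
                      meta = list()) {
  heights <- as.matrix(heights)
  if (!is.numeric(heights) || any(!is.finite(heights))) {
    stop_domain("heights must be a finite numeric matrix")
  }
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    stop_domain("pixel_size must be positive")
  }
  structure(list(heights = heights, pixel_size = pixel_size,
                 background = background, meta = meta), class = "afm_image")
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf("AFM image: %d x %d px at %.3g nm/px (%.3g x %.3g nm)\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              ncol(x$heights) * x$pixel_size, nrow(x$heights) * x$pixel_size))
  invisible(x)
}

#' Integrated molecular volume of an AFM image
#'
#' `sum(max(h - background, 0)) * pixel_size^2` over all pixels. The
#' background defaults to the image's recorded background, falling back to
#' the image median (molecules occupy a small area fraction). An optional
#' `noise_floor` (nm) zeroes pixels within that margin of the background
#' before integration, suppressing the positive half of the background
#' noise.
#'
#' @param image An [afm_image()].
#' @param background Background level in nm; `NULL` to use the recorded or
#'   median background.
#' @param noise_floor Margin above background below which pixels are
#'   ignored, in nm. Default 0.
#'
#' @return Integrated volume in nm^3.
#' @export
integrated_volume <- function(image, background = NULL, noise_floor = 0) {
  stopifnot(inherits(image, "afm_image"))
  bg <- background %||%
    (if (!is.na(image$background)) image$background
     else stats::median(image$heights))
  h <- image$heights - bg
  if (noise_floor > 0) h[h < noise_floor] <- 0
  sum(pmax(h, 0)) * image$pixel_size^2
}

#' Trace the backbone of a synthetic AFM image
#'
#' Ridge-following on a thresholded skeleton, intended for images produced
#' by [gen_afm_image()] (general-purpose tracing of experimental AFM scans
#' is out of scope). Pixels above the half-maximum over background are
#' chained greedily from an endpoint to the nearest unvisited skeleton
#' pixel; chaining stops when the nearest remaining pixel is more than
#' `2 * pixel_size` away.
#'
#' @param image An [afm_image()].
#' @param threshold Height threshold in nm; defaults to background plus half
#'   the maximum height above background.
#'
#' @return A [backbone_trace()] of pixel-center coordinates in nm.
#' @export
trace_afm_skeleton <- function(image, threshold = NULL) {
  stopifnot(inherits(image, "afm_image"))
  bg <- if (!is.na(image$background)) image$background
        else stats::median(image$heights)
  thr <- threshold %||% (bg + 0.5 * (max(image$heights) - bg))
  px <- image$pixel_size
  h <- image$heights
  nr <- nrow(h); nc <- ncol(h)
  ## ridge thinning: keep pixels that are strict local maxima across the
  ## ridge (along rows or along columns), so a blurred line collapses to
  ## its single-pixel crest
  eps <- 1e-9
  up <- rbind(h[-1, , drop = FALSE], -Inf)
  down <- rbind(-Inf, h[-nr, , drop = FALSE])
  left <- cbind(-Inf, h[, -nc, drop = FALSE])
  right <- cbind(h[, -1, drop = FALSE], -Inf)
  ridge <- (h >= up + eps & h >= down + eps) |
    (h >= left + eps & h >= right + eps)
  idx <- which(h > thr & ridge, arr.ind = TRUE)
  if (nrow(idx) < 3) stop_insufficient("fewer than 3 pixels above threshold")
  pts <- cbind(x = (idx[, "col"] - 0.5) * px, y = (idx[, "row"] - 0.5) * px)
  ## start from the pixel farthest from the centroid (an endpoint)
  ctr <- colMeans(pts)
  cur <- which.max((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  n <- nrow(pts)
  order_idx <- integer(n)
  used <- rep(FALSE, n)
  order_idx[1] <- cur; used[cur] <- TRUE
  count <- 1L
  max_jump2 <- (2 * px)^2
  while (count < n) {
    d2 <- (pts[, 1] - pts[cur, 1])^2 + (pts[, 2] - pts[cur, 2])^2
    d2[used] <- Inf
    nxt <- which.min(d2)
    if (!is.finite(d2[nxt]) || d2[nxt] > max_jump2) break
    count <- count + 1L
    order_idx[count] <- nxt
    used[nxt] <- TRUE
    cur <- nxt
  }
  keep <- order_idx[seq_len(count)]
  new_backbone_trace(pts[keep, , drop = FALSE],
                     molecule_id = "skeleton", meta = list())
}
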