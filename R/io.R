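## ---- delimited text with '# key=value' metadata headers ----

parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    kv <- strsplit(body, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  meta
}

read_table_meta <- function(path) {
  if (!file.exists(path)) stop_domain(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- parse_meta_lines(lines[is_meta])
  body <- lines[!is_meta & nzchar(lines)]
  if (!length(body)) stop_domain(paste("no data rows in", path))
  sep <- if (grepl(",", body[1])) "," else ""
  tab <- utils::read.table(text = body, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  list(meta = meta, table = tab)
}

require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop_domain(sprintf("%s: missing required column(s) %s", path,
                        paste(sQuote(missing), collapse = ", ")))
  }
}

write_table_meta <- function(tab, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }
  for (key in names(meta)) {
    val <- meta[[key]]
    if (is.null(val) || length(val) != 1 || is.list(val)) next
    writeLines(sprintf("# %s=%s", key, fmt(val)), con)
  }
  tab[] <- lapply(tab, fmt)  # full double precision round-trip
  utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a force-extension curve from delimited text
#'
#' Expects columns `force_pN` and `extension_nm` (CSV or whitespace
#' delimited) with optional `# key=value` metadata header lines (`n_nt`,
#' `direction`, `substrate`, `protein`, `concentration_nM`, ...).
#'
#' @param path File path.
#' @return A [force_extension_curve()].
#' @export
read_fec <- function(path) {
  r <- read_table_meta(path)
  require_columns(r$table, c("force_pN", "extension_nm"), path)
  direction <- r$meta$direction %||% "stretch"
  r$meta$direction <- NULL
  force_extension_curve(r$table$force_pN, r$table$extension_nm,
                        direction = direction, meta = r$meta)
}

#' Write a force-extension curve to delimited text
#'
#' @param fec A [force_extension_curve()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fec <- function(fec, path) {
  stopifnot(inherits(fec, "fec"))
  meta <- fec$meta
  meta$truth <- NULL
  meta$direction <- fec$direction
  write_table_meta(data.frame(force_pN = fec$force,
                              extension_nm = fec$extension),
                   meta, path)
}

#' Read a time-extension trace from delimited text
#'
#' Expects columns `time_s` and `extension_nm`, with optional metadata
#' header lines `force_pN`, `concentration_nM` and `phase`.
#'
#' @param path File path.
#' @return A [time_extension_trace()].
#' @export
read_trace <- function(path) {
  r <- read_table_meta(path)
  require_columns(r$table, c("time_s", "extension_nm"), path)
  phase <- r$meta$phase %||% "binding"
  time_extension_trace(r$table$time_s, r$table$extension_nm,
                       force = r$meta$force_pN %||% NA_real_,
                       concentration = r$meta$concentration_nM %||% NA_real_,
                       phase = phase,
                       meta = r$meta[setdiff(names(r$meta),
                                             c("force_pN", "concentration_nM",
                                               "phase"))])
}

#' Write a time-extension trace to delimited text
#'
#' @param trace A [time_extension_trace()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "tet"))
  meta <- trace$meta
  meta$truth <- NULL
  meta$force_pN <- trace$force
  meta$concentration_nM <- trace$concentration
  meta$phase <- trace$phase
  meta <- meta[!vapply(meta, function(v) length(v) == 1 && is.na(v), logical(1))]
  write_table_meta(data.frame(time_s = trace$time,
                              extension_nm = trace$extension),
                   meta, path)
}

#' Read a rate series from CSV
#'
#' Expects columns `abscissa` and `rate`, optionally `uncertainty`.
#'
#' @param path File path.
#' @return A [rate_series()].
#' @export
read_rate_series <- function(path) {
  r <- read_table_meta(path)
  require_columns(r$table, c("abscissa", "rate"), path)
  rate_series(r$table$abscissa, r$table$rate,
              uncertainties = r$table$uncertainty)
}

#' Write a rate series to CSV
#'
#' @param series A [rate_series()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rate_series <- function(series, path) {
  stopifnot(inherits(series, "rate_series"))
  tab <- data.frame(abscissa = series$abscissa, rate = series$rates)
  if (!is.null(series$uncertainties)) tab$uncertainty <- series$uncertainties
  write_table_meta(tab, list(), path)
}

#' Read an AFM image from a plain-text numeric grid
#'
#' The grid is whitespace-delimited heights in nm (one image row per line);
#' a JSON sidecar (`<path>.json` by default) supplies `pixel_size` and
#' optionally `background`.
#'
#' @param path Grid file path.
#' @param sidecar Sidecar JSON path.
#' @return An [afm_image()].
#' @export
read_afm_image <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop_domain(paste("file not found:", path))
  if (!file.exists(sidecar)) stop_domain(paste("sidecar not found:", sidecar))
  side <- jsonlite::fromJSON(sidecar)
  if (is.null(side$pixel_size)) {
    stop_domain(paste(sidecar, "must define pixel_size"))
  }
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  afm_image(m, as.numeric(side$pixel_size),
            background = as.numeric(side$background %||% NA_real_))
}

#' Write an AFM image as a plain-text numeric grid plus JSON sidecar
#'
#' @param image An [afm_image()].
#' @param path Grid file path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_afm_image <- function(image, path) {
  stopifnot(inherits(image, "afm_image"))
  utils::write.table(image$heights, path, row.names = FALSE,
                     col.names = FALSE)
  side <- list(pixel_size = image$pixel_size)
  if (!is.na(image$background)) side$background <- image$background
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

## strip unserializable members (nls fits) from result objects
fit_record <- function(x) {
  if (inherits(x, "polymer_fit")) {
    return(list(model = x$model,
                params = unclass(x$params),
                param_uncertainties = as.list(x$param_uncertainties),
                force_window = x$force_window,
                residual_rms = x$residual_rms, n = x$n))
  }
  if (is.list(x)) {
    x <- unclass(x)
    x$fit <- NULL
    return(lapply(x, function(e) if (is.list(e)) fit_record(e) else e))
  }
  x
}

#' Serialize an analysis result to JSON
#'
#' Writes any of the package's fit/decomposition objects (with internal
#' model objects stripped) as a JSON record at full double precision.
#'
#' @param x A result object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_result <- function(x, path) {
  jsonlite::write_json(fit_record(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
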