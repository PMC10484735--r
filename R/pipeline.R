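#' Pipeline run configuration
#'
#' Collects the tunable analysis parameters in one validated object.
#'
#' @param kBT Thermal energy in pN nm. Default 4.11.
#' @param fjc_f_max FJC fit window cap in pN. Default 10.
#' @param wlc_f_max WLC fit window cap in pN. Default 5.
#' @param bin_width Force bin width in pN. Default 1.
#' @param smooth_window Binding-trace smoothing window in s. Default 1.
#' @param min_depth_sd Phase-presence threshold in noise SDs. Default 3.
#' @param resample_step AFM resample step in nm. Default 5.
#' @param contact_radius AFM loop-contact radius in nm. Default 4.
#' @param seed Integer seed recorded in reports. Default 1.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(kBT = 4.11, fjc_f_max = 10, wlc_f_max = 5,
                       bin_width = 1, smooth_window = 1, min_depth_sd = 3,
                       resample_step = 5, contact_radius = 4, seed = 1L) {
  stopifnot(kBT > 0, fjc_f_max > 0, wlc_f_max > 0, bin_width > 0,
            smooth_window > 0, min_depth_sd > 0, resample_step > 0,
            contact_radius > 0)
  structure(list(kBT = kBT, fjc_f_max = fjc_f_max, wlc_f_max = wlc_f_max,
                 bin_width = bin_width, smooth_window = smooth_window,
                 min_depth_sd = min_depth_sd, resample_step = resample_step,
                 contact_radius = contact_radius, seed = as.integer(seed)),
            class = "run_config")
}

run_stage <- function(report, stage, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE,
                                           error = conditionMessage(e)))
  if (res$ok) {
    report$stages[[stage]] <- res$value
  } else {
    report$errors[[stage]] <- res$error
  }
  report
}

#' Run the analysis pipeline over a set of inputs
#'
#' Executes the configured stages over typed inputs and collects results and
#' per-stage errors into a report. Inputs may be in-memory objects or file
#' paths (read with the package readers); a corrupt file fails only its own
#' stage entry. With `out_dir` set, the report is written as
#' `report.json` (full precision, no timestamps, so identical inputs and
#' config give byte-identical reports).
#'
#' @param inputs A named list with any of: `fec` (list of
#'   [force_extension_curve()] or paths; fit per `fec_model`), `fec_model`
#'   (`"fjc"` or `"wlc"`), `fec_n_nt` substrate length, `binding_traces`,
#'   `dissociation_traces` (lists of [time_extension_trace()] or paths),
#'   `force_rates`, `concentration_rates` ([rate_series()] or paths),
#'   `helix` (argument list for [helix_parameters()]), `afm_traces` (list of
#'   [backbone_trace()]).
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL`.
#'
#' @return A list of class `pipeline_report` with `config`, `stages`,
#'   `errors` and `success`.
#' @export
run_pipeline <- function(inputs = list(), config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  const <- sm_constants(kBT = config$kBT)
  report <- list(package_version = as.character(utils::packageVersion("ssbfil")),
                 config = unclass(config), stages = list(), errors = list())

  as_obj <- function(x, reader) if (is.character(x)) reader(x) else x

  fecs <- inputs$fec %||% list()
  model <- inputs$fec_model %||% "fjc"
  for (i in seq_along(fecs)) {
    nm <- paste0("fec_", names(fecs)[i] %||% i)
    if (is.null(names(fecs)) || !nzchar(names(fecs)[i])) nm <- paste0("fec_", i)
    report <- run_stage(report, nm, {
      fec <- as_obj(fecs[[i]], read_fec)
      fit <- if (identical(model, "wlc")) {
        fit_wlc(fec, f_max = config$wlc_f_max, n_nt = inputs$fec_n_nt,
                constants = const)
      } else {
        fit_fjc(fec, f_max = config$fjc_f_max, n_nt = inputs$fec_n_nt,
                constants = const)
      }
      fit_record(fit)
    })
  }

  for (i in seq_along(inputs$binding_traces %||% list())) {
    report <- run_stage(report, paste0("binding_", i), {
      tr <- as_obj(inputs$binding_traces[[i]], read_trace)
      fit_record(decompose_binding_trace(tr,
                                         smooth_window = config$smooth_window,
                                         min_depth_sd = config$min_depth_sd))
    })
  }

  for (i in seq_along(inputs$dissociation_traces %||% list())) {
    report <- run_stage(report, paste0("dissociation_", i), {
      tr <- as_obj(inputs$dissociation_traces[[i]], read_trace)
      fit_record(decompose_dissociation_trace(tr))
    })
  }

  if (!is.null(inputs$force_rates)) {
    report <- run_stage(report, "bell", {
      fit_record(fit_bell(as_obj(inputs$force_rates, read_rate_series),
                          constants = const))
    })
  }
  if (!is.null(inputs$concentration_rates)) {
    report <- run_stage(report, "bimolecular", {
      fit_record(fit_bimolecular(as_obj(inputs$concentration_rates,
                                        read_rate_series)))
    })
  }

  if (!is.null(inputs$helix)) {
    report <- run_stage(report, "helix", {
      fit_record(do.call(helix_parameters, inputs$helix))
    })
  }

  if (!is.null(inputs$afm_traces)) {
    report <- run_stage(report, "afm", {
      traces <- lapply(inputs$afm_traces, as_obj, reader = function(p)
        stop_domain("afm trace inputs must be backbone_trace objects"))
      loopfree <- lapply(traces, longest_loopfree_segment,
                         contact_radius = config$contact_radius)
      prof <- tangent_correlation(loopfree,
                                  resample_step = config$resample_step)
      pfit <- fit_persistence_2d(prof)
      list(contour_lengths = vapply(traces, trace_contour_length,
                                    numeric(1)),
           persistence = fit_record(pfit))
    })
  }

  report$success <- length(report$errors) == 0
  class(report) <- "pipeline_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report: %d stage(s) succeeded, %d failed\n",
              length(x$stages), length(x$errors)))
  for (nm in names(x$errors)) cat(sprintf("  FAILED %s: %s\n", nm,
                                          x$errors[[nm]]))
  invisible(x)
}
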