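# Machine tolerance configuration.
#
# The vendor's clinical alarm/abort thresholds are proprietary, so every
# tolerance is configurable; defaults follow the published machine
# characteristics: +/-1 mm on spot position (systematic and per-spot random
# components checked separately), +/-10% on spot size relative to the
# commissioning baseline, and deliverable spot MU in [0.003, 5] MU.

#' Tolerance configuration for spot QA
#'
#' @param pos_systematic_mm Tolerance on the per-layer systematic position
#'   shift (mean spot deviation), mm. Default 1.0.
#' @param pos_random_mm Tolerance on each spot's random residual
#'   (deviation minus the layer mean), mm. Default 1.0.
#' @param size_percent Relative tolerance on the layer-mean delivered spot
#'   size versus the commissioning baseline, percent. Default 10.
#' @param mu_abs Absolute tolerance on per-spot delivered minus planned MU.
#'   Default 0.001 MU.
#' @param mu_min,mu_max Minimum and maximum deliverable MU per spot.
#'   Defaults 0.003 and 5 MU.
#' @return A `tolerance_config` object (a named list).
#' @export
tolerance_config <- function(pos_systematic_mm = 1.0,
                             pos_random_mm = 1.0,
                             size_percent = 10.0,
                             mu_abs = 0.001,
                             mu_min = 0.003,
                             mu_max = 5.0) {
  cfg <- list(
    pos_systematic_mm = pos_systematic_mm,
    pos_random_mm = pos_random_mm,
    size_percent = size_percent,
    mu_abs = mu_abs,
    mu_min = mu_min,
    mu_max = mu_max
  )
  bad <- names(cfg)[!vapply(cfg, function(v) is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0, logical(1))]
  if (length(bad) > 0) {
    qa_abort(paste0("tolerance fields must be single positive numbers: ",
                    paste(bad, collapse = ", ")), "qa_config_error")
  }
  if (cfg$mu_min >= cfg$mu_max) {
    qa_abort("mu_min must be below mu_max", "qa_config_error")
  }
  structure(cfg, class = "tolerance_config")
}

#' Read a tolerance configuration from YAML or JSON
#'
#' Unknown fields are rejected; absent fields take the defaults of
#' [tolerance_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are the
#'   field names of [tolerance_config()].
#' @return A `tolerance_config` object.
#' @export
read_tolerance_config <- function(path) {
  if (!file.exists(path)) {
    qa_abort(paste0("no such file: ", path), "qa_io_error")
  }
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(tolerance_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    qa_abort(paste0("unknown tolerance fields: ", paste(unknown, collapse = ", ")),
             "qa_config_error")
  }
  do.call(tolerance_config, vals)
}

#' @export
print.tolerance_config <- function(x, ...) {
  cat("<tolerance_config>\n")
  cat(sprintf("  position: systematic %.3g mm, random %.3g mm per spot\n",
              x$pos_systematic_mm, x$pos_random_mm))
  cat(sprintf("  size:     +/-%.3g%% of baseline\n", x$size_percent))
  cat(sprintf("  MU:       |delivered - planned| <= %.3g MU; deliverable [%g, %g] MU\n",
              x$mu_abs, x$mu_min, x$mu_max))
  invisible(x)
}
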