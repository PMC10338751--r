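# JSON serialization of QA reports.
#
# Schema: {session: {...}, pass, tool_version, config: {...},
#          layers: [...], spots: [...],
#          flags: [{kind, axis, field_id, layer_index, spot_index|null,
#                   value, tolerance}, ...],
#          summary: {<metric>: {n, mean, sd}, ...}}

#' Write / read a QA report as JSON
#'
#' @param report A `qa_report` from [qa_check()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "qa_report"))
  metrics <- c("d_x_mm", "d_y_mm", "d_mu", "d_mu_percent")
  summary <- lapply(setNames(metrics, metrics), function(m) {
    v <- report$spots[[m]]
    list(n = length(v), mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  obj <- list(
    session = as.list(report$session),
    pass = report$pass,
    tool_version = report$tool_version,
    config = unclass(report$config),
    layers = report$layers,
    spots = report$spots,
    flags = report$flags,
    summary = summary
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @return `read_report`: the `qa_report` reconstructed from JSON.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) qa_abort(paste0("no such file: ", path), "qa_io_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  flags <- as_tibble(obj$flags)
  if (nrow(flags) == 0) {
    flags <- tibble(kind = character(0), axis = character(0),
                    field_id = character(0), layer_index = numeric(0),
                    spot_index = numeric(0), value = numeric(0),
                    tolerance = numeric(0))
  }
  new_qa_report(
    meta = as_tibble(obj$session),
    spots = as_tibble(obj$spots),
    layers = as_tibble(obj$layers),
    flags = flags,
    config = do.call(tolerance_config, obj$config)
  )
}
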