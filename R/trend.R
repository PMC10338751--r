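# Fleet-level trend aggregation across QA sessions.
#
# Pools per-spot metrics (MU difference, MU percent difference, random
# residuals, planned energy and MU) and per-layer metrics (systematic
# shifts, size deviations) over many reports and summarises them overall
# or stratified by room. The two half-gantry rooms G1 and G2 share a beam
# model and are interchangeable, so they are additionally reported merged
# as "G1+G2"; the fixed-room standard and micro-beam modes stay separate.
# SD is the sample standard deviation (n - 1 denominator).

SPOT_METRICS <- c(d_mu = "d_mu", d_mu_percent = "d_mu_percent",
                  random_x_mm = "random_x_mm", random_y_mm = "random_y_mm",
                  planned_energy_MeV = "energy_MeV", planned_mu = "mu_plan")
LAYER_METRICS <- c(systematic_x_mm = "systematic_x_mm",
                   systematic_y_mm = "systematic_y_mm",
                   size_dev_x_mm = "size_dev_x_mm",
                   size_dev_y_mm = "size_dev_y_mm")

summarise_metric <- function(values, metric, stratum) {
  values <- values[!is.na(values)]
  tibble(
    stratum = stratum, metric = metric, n = length(values),
    mean = if (length(values) > 0) mean(values) else NA_real_,
    sd = if (length(values) > 1) stats::sd(values) else NA_real_,
    min = if (length(values) > 0) min(values) else NA_real_,
    max = if (length(values) > 0) max(values) else NA_real_
  )
}

#' Aggregate QA reports into fleet trend summaries
#'
#' @param reports A list of `qa_report` objects (or a single report).
#' @param strata `"all"` for one pooled stratum, `"room"` for per-room
#'   summaries (with G1 and G2 also merged as `"G1+G2"`).
#' @return A tibble with one row per (stratum, metric): `n`, `mean`, `sd`,
#'   `min`, `max`. The pooled mean over sessions equals the
#'   observation-count-weighted mean of per-session means exactly.
#' @export
aggregate_reports <- function(reports, strata = c("all", "room")) {
  strata <- match.arg(strata)
  if (inherits(reports, "qa_report")) reports <- list(reports)
  if (length(reports) == 0) qa_abort("no reports to aggregate", "qa_domain_error")
  stopifnot(all(vapply(reports, inherits, logical(1), "qa_report")))

  spots <- list_rbind(lapply(reports, function(r) {
    mutate(r$spots, room = r$session$room)
  }))
  layers <- list_rbind(lapply(reports, function(r) {
    mutate(r$layers, room = r$session$room)
  }))

  groups <- if (strata == "all") {
    list(all = list(spots = spots, layers = layers))
  } else {
    rooms <- unique(c(spots$room, layers$room))
    g <- lapply(setNames(rooms, rooms), function(rm) {
      list(spots = spots[spots$room == rm, ], layers = layers[layers$room == rm, ])
    })
    if (all(c("G1", "G2") %in% rooms)) {
      g[["G1+G2"]] <- list(spots = spots[spots$room %in% c("G1", "G2"), ],
                           layers = layers[layers$room %in% c("G1", "G2"), ])
    }
    g
  }

  list_rbind(imap(groups, function(grp, key) {
    bind_rows(
      list_rbind(imap(SPOT_METRICS, function(col, m) {
        summarise_metric(grp$spots[[col]], m, key)
      })),
      list_rbind(imap(LAYER_METRICS, function(col, m) {
        summarise_metric(grp$layers[[col]], m, key)
      }))
    )
  }))
}

#' Histogram counts over fixed bin edges
#'
#' Bins are half-open `[e_i, e_{i+1})` with the last bin closed, so the
#' counts total the number of in-range values.
#'
#' @param values Numeric vector.
#' @param edges Strictly increasing numeric vector of bin edges.
#' @return Tibble with `bin_left`, `bin_right`, `count`.
#' @export
qa_histogram <- function(values, edges) {
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    qa_abort("bin edges must be strictly increasing", "qa_domain_error")
  }
  values <- values[!is.na(values)]
  k <- findInterval(values, edges, rightmost.closed = TRUE)
  k <- k[k >= 1 & k <= length(edges) - 1]
  counts <- tabulate(k, nbins = length(edges) - 1)
  tibble(bin_left = edges[-length(edges)], bin_right = edges[-1], count = counts)
}

#' Export a trend summary
#'
#' @param summary Tibble from [aggregate_reports()].
#' @param path Output path ending in `.csv` or `.json`.
#' @export
write_trend_summary <- function(summary, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  } else {
    utils::write.csv(summary, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
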