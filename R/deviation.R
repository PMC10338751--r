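# Per-spot deviations and the systematic/random decomposition.
#
# For every matched spot the deviation is delivered minus planned,
# component-wise on X, Y and MU. Within one energy layer the positional
# deviations split exactly into
#
#   systematic = mean over the layer's spots   (block shift of the layer)
#   random_i   = deviation_i - systematic      (scatter about the centroid)
#
# so deviation_i = systematic + random_i holds identically and the random
# residuals sum to zero per layer and axis. The systematic component is
# checked against the layer-shift tolerance, every random residual against
# the per-spot tolerance; MU differences are checked per spot and sizes
# per layer against the commissioning baseline.

#' Per-spot deviations between delivered and planned spots
#'
#' @param paired Output of [pair_spots()].
#' @return The input with columns `d_x_mm`, `d_y_mm` (delivered - planned,
#'   mm), `d_mu` (MU) and `d_mu_percent` (percent of planned MU) appended.
#' @export
spot_deviations <- function(paired) {
  check_spot_frame(paired, c("x_plan", "y_plan", "mu_plan", "x_del", "y_del", "mu_del"),
                   "paired spots")
  mutate(
    as_tibble(paired),
    d_x_mm = .data$x_del - .data$x_plan,
    d_y_mm = .data$y_del - .data$y_plan,
    d_mu = .data$mu_del - .data$mu_plan,
    d_mu_percent = 100 * (.data$mu_del - .data$mu_plan) / .data$mu_plan
  )
}

#' Systematic (layer-shift) component of positional deviations
#'
#' The mean of the per-spot deviations over the layer's accumulated
#' spots: the shift of the whole layer from its planned centroid.
#'
#' @param deviations Numeric vector of per-spot deviations on one axis (mm).
#' @return Scalar layer shift (mm).
#' @export
layer_systematic_error <- function(deviations) {
  if (length(deviations) == 0) {
    qa_abort("empty layer: systematic error undefined", "qa_domain_error")
  }
  mean(deviations)
}

#' Random (per-spot scatter) component of positional deviations
#'
#' Each spot's displacement from the layer centroid: the deviation minus
#' the layer's systematic shift. Residuals sum to zero by construction.
#'
#' @inheritParams layer_systematic_error
#' @return Numeric vector of residuals, same length as the input (mm).
#' @export
layer_random_errors <- function(deviations) {
  if (length(deviations) == 0) {
    qa_abort("empty layer: random errors undefined", "qa_domain_error")
  }
  deviations - mean(deviations)
}

#' Layer size deviation against the commissioning baseline
#'
#' Compares the layer-mean delivered spot sigma per axis with the
#' commissioning baseline at the layer's energy and gantry angle. Sizes
#' are a per-layer quantity on the modelled machine, so the delivered
#' sigmas are averaged over the layer before comparison.
#'
#' @param delivered_layer Tibble of the layer's delivered spots (needs
#'   `energy_MeV`, `sigma_x_mm`, `sigma_y_mm`).
#' @param baseline A [size_baseline()].
#' @param gantry_angle_deg Gantry angle of the field (degrees).
#' @return One-row tibble: baseline and delivered sigmas, `size_dev_x_mm`,
#'   `size_dev_y_mm` and the corresponding percent deviations.
#' @export
layer_size_deviation <- function(delivered_layer, baseline, gantry_angle_deg) {
  check_spot_frame(delivered_layer, c("energy_MeV", "sigma_x_mm", "sigma_y_mm"),
                   "delivered layer")
  ref <- baseline_sigma(baseline, delivered_layer$energy_MeV[1], gantry_angle_deg)
  sx <- mean(delivered_layer$sigma_x_mm, na.rm = TRUE)
  sy <- mean(delivered_layer$sigma_y_mm, na.rm = TRUE)
  tibble(
    baseline_sigma_x_mm = ref[["sigma_x_mm"]],
    baseline_sigma_y_mm = ref[["sigma_y_mm"]],
    delivered_sigma_x_mm = sx,
    delivered_sigma_y_mm = sy,
    size_dev_x_mm = sx - ref[["sigma_x_mm"]],
    size_dev_y_mm = sy - ref[["sigma_y_mm"]],
    size_dev_x_percent = 100 * (sx - ref[["sigma_x_mm"]]) / ref[["sigma_x_mm"]],
    size_dev_y_percent = 100 * (sy - ref[["sigma_y_mm"]]) / ref[["sigma_y_mm"]]
  )
}

flag_row <- function(kind, axis, field_id, layer_index, spot_index, value, tolerance) {
  tibble(kind = kind, axis = axis, field_id = field_id,
         layer_index = layer_index, spot_index = spot_index,
         value = value, tolerance = tolerance)
}

evaluate_layer <- function(dev_layer, baseline, config) {
  fid <- dev_layer$field_id[1]
  li <- dev_layer$layer_index[1]
  n <- nrow(dev_layer)
  sys_x <- layer_systematic_error(dev_layer$d_x_mm)
  sys_y <- layer_systematic_error(dev_layer$d_y_mm)
  rnd_x <- layer_random_errors(dev_layer$d_x_mm)
  rnd_y <- layer_random_errors(dev_layer$d_y_mm)

  flags <- list()
  add <- function(f) flags[[length(flags) + 1]] <<- f
  if (abs(sys_x) > config$pos_systematic_mm)
    add(flag_row("systematic", "x", fid, li, NA_real_, sys_x, config$pos_systematic_mm))
  if (abs(sys_y) > config$pos_systematic_mm)
    add(flag_row("systematic", "y", fid, li, NA_real_, sys_y, config$pos_systematic_mm))
  for (i in which(abs(rnd_x) > config$pos_random_mm))
    add(flag_row("random", "x", fid, li, dev_layer$spot_index[i], rnd_x[i], config$pos_random_mm))
  for (i in which(abs(rnd_y) > config$pos_random_mm))
    add(flag_row("random", "y", fid, li, dev_layer$spot_index[i], rnd_y[i], config$pos_random_mm))
  for (i in which(abs(dev_layer$d_mu) > config$mu_abs))
    add(flag_row("mu", NA_character_, fid, li, dev_layer$spot_index[i],
                 dev_layer$d_mu[i], config$mu_abs))

  size <- NULL
  if (!is.null(baseline) && !all(is.na(dev_layer$sigma_x_mm))) {
    size <- layer_size_deviation(dev_layer, baseline, dev_layer$gantry_angle_deg[1])
    if (abs(size$size_dev_x_percent) > config$size_percent)
      add(flag_row("size", "x", fid, li, NA_real_, size$size_dev_x_percent, config$size_percent))
    if (abs(size$size_dev_y_percent) > config$size_percent)
      add(flag_row("size", "y", fid, li, NA_real_, size$size_dev_y_percent, config$size_percent))
  } else {
    size <- tibble(baseline_sigma_x_mm = NA_real_, baseline_sigma_y_mm = NA_real_,
                   delivered_sigma_x_mm = NA_real_, delivered_sigma_y_mm = NA_real_,
                   size_dev_x_mm = NA_real_, size_dev_y_mm = NA_real_,
                   size_dev_x_percent = NA_real_, size_dev_y_percent = NA_real_)
  }

  layer_summary <- dplyr::bind_cols(
    tibble(field_id = fid, layer_index = li,
           energy_MeV = dev_layer$energy_MeV[1],
           gantry_angle_deg = dev_layer$gantry_angle_deg[1],
           n_spots = n,
           systematic_x_mm = sys_x, systematic_y_mm = sys_y,
           random_sd_x_mm = if (n > 1) stats::sd(rnd_x) else 0,
           random_sd_y_mm = if (n > 1) stats::sd(rnd_y) else 0),
    size
  )
  spots <- mutate(dev_layer, random_x_mm = rnd_x, random_y_mm = rnd_y)
  list(spots = spots, layer = layer_summary, flags = list_rbind(flags))
}

#' Evaluate one field's delivery against its plan
#'
#' Pairs spots, computes per-spot deviations, decomposes each layer's
#' positional deviations into systematic and random components, compares
#' layer sizes with the commissioning baseline, and checks every quantity
#' against the machine tolerances. Each violation yields one flag naming
#' the kind, axis, layer and (for per-spot checks) the exact spot.
#'
#' @param plan Plan tibble for a single field.
#' @param delivered Delivered spots for the same field.
#' @param baseline A [size_baseline()], or `NULL` to skip size checks.
#' @param config A [tolerance_config()].
#' @return List with `spots`, `layers`, `flags` tibbles.
#' @export
evaluate_field <- function(plan, delivered, baseline = NULL,
                           config = tolerance_config()) {
  paired <- pair_spots(plan, delivered)
  dev <- spot_deviations(paired)
  parts <- lapply(split(dev, paste(dev$field_id, dev$layer_index)),
                  evaluate_layer, baseline = baseline, config = config)
  spots <- order_plan(list_rbind(lapply(parts, `[[`, "spots")))
  layers <- dplyr::arrange(list_rbind(lapply(parts, `[[`, "layer")),
                           .data$field_id, .data$layer_index)
  flags <- list_rbind(lapply(parts, `[[`, "flags"))
  if (nrow(flags) > 0) flags <- dplyr::arrange(flags, .data$field_id, .data$layer_index)
  list(spots = spots, layers = layers, flags = flags)
}

#' Run log-file QA for a delivery session
#'
#' Evaluates every field of a session against the plan and assembles a QA
#' report: per-spot deviations, per-layer systematic/random/size
#' summaries, tolerance flags and the overall pass verdict (pass is true
#' iff no flag was raised anywhere).
#'
#' @param plan Plan tibble covering the session's fields.
#' @param session Session tibble from [read_delivery_log()] or
#'   [simulate_delivery()].
#' @param baseline A [size_baseline()], or `NULL` to skip size checks.
#' @param config A [tolerance_config()].
#' @return A `qa_report` object; see [tidy.qa_report()] and
#'   [glance.qa_report()].
#' @export
qa_check <- function(plan, session, baseline = NULL, config = tolerance_config()) {
  check_plan_frame(plan)
  check_log_frame(session)
  res <- evaluate_field(plan, session, baseline, config)
  meta <- distinct(as_tibble(session)[c("session_id", "room", "date")])
  if (nrow(meta) != 1) {
    qa_abort("session tibble must describe exactly one session", "qa_domain_error")
  }
  new_qa_report(meta, res$spots, res$layers, res$flags, config)
}

new_qa_report <- function(meta, spots, layers, flags, config) {
  structure(
    list(session = meta, spots = spots, layers = layers, flags = flags,
         pass = nrow(flags) == 0, config = config,
         tool_version = as.character(utils::packageVersion("spotqa"))),
    class = "qa_report"
  )
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> session %s (room %s, %s)\n",
              x$session$session_id, x$session$room, x$session$date))
  cat(sprintf("  %d spots in %d layers across %d field(s)\n",
              nrow(x$spots), nrow(x$layers), length(unique(x$layers$field_id))))
  cat(sprintf("  flags: %d  ->  %s\n", nrow(x$flags), if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Tidy a QA report
#'
#' @param x A `qa_report`.
#' @param level `"spot"` (per-spot deviations and random residuals),
#'   `"layer"` (per-layer systematic/random/size summaries) or `"flag"`.
#' @param ... Unused.
#' @return A tibble at the requested granularity.
#' @method tidy qa_report
#' @export
tidy.qa_report <- function(x, level = c("spot", "layer", "flag"), ...) {
  level <- match.arg(level)
  switch(level, spot = x$spots, layer = x$layers, flag = x$flags)
}

#' One-row summary of a QA report
#'
#' @param x A `qa_report`.
#' @param ... Unused.
#' @return One-row tibble: spot/layer/flag counts, largest absolute
#'   systematic shift and random residual, mean MU difference, pass.
#' @method glance qa_report
#' @export
glance.qa_report <- function(x, ...) {
  tibble(
    session_id = x$session$session_id,
    room = x$session$room,
    n_fields = length(unique(x$layers$field_id)),
    n_layers = nrow(x$layers),
    n_spots = nrow(x$spots),
    n_flags = nrow(x$flags),
    max_abs_systematic_mm = max(abs(c(x$layers$systematic_x_mm, x$layers$systematic_y_mm))),
    max_abs_random_mm = max(abs(c(x$spots$random_x_mm, x$spots$random_y_mm))),
    mean_d_mu = mean(x$spots$d_mu),
    pass = x$pass
  )
}
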