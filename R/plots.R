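# Plotting. Figures mirror the standard trend views: per-spot deviation
# scatter, systematic/random distributions, planned-energy and MU
# histograms, and dose / gamma maps.

#' @method autoplot qa_report
#' @export
autoplot.qa_report <- function(object, ...) {
  spots <- tidyr::pivot_longer(object$spots, c("d_x_mm", "d_y_mm"),
                               names_to = "axis", values_to = "deviation_mm")
  spots$axis <- ifelse(spots$axis == "d_x_mm", "X", "Y")
  ggplot2::ggplot(spots, ggplot2::aes(x = .data$energy_MeV, y = .data$deviation_mm)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "Energy (MeV)", y = "Delivered - planned position (mm)",
                  title = sprintf("Spot position deviations, session %s",
                                  object$session$session_id))
}

#' Histogram figure of planned spot energies and MU
#'
#' @param plan Plan tibble.
#' @param bins Bin count per panel. Default 40.
#' @return A ggplot object with one panel per quantity.
#' @export
plot_plan_histograms <- function(plan, bins = 40) {
  check_plan_frame(plan)
  long <- tidyr::pivot_longer(plan[c("energy_MeV", "mu")],
                              dplyr::everything(),
                              names_to = "quantity", values_to = "value")
  long$quantity <- ifelse(long$quantity == "energy_MeV",
                          "Planned energy (MeV)", "Planned spot MU")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = NULL, y = "Spots")
}

#' Trend figure of per-layer systematic and per-spot random errors
#'
#' @param reports List of `qa_report` objects.
#' @return A ggplot object, one panel per axis and error component.
#' @export
plot_position_trends <- function(reports) {
  if (inherits(reports, "qa_report")) reports <- list(reports)
  layers <- list_rbind(lapply(reports, function(r) {
    mutate(r$layers, room = r$session$room, date = r$session$date)
  }))
  long <- tidyr::pivot_longer(layers, c("systematic_x_mm", "systematic_y_mm"),
                              names_to = "axis", values_to = "mm")
  long$axis <- ifelse(grepl("_x_", long$axis), "Systematic X", "Systematic Y")
  spots <- list_rbind(lapply(reports, function(r) {
    mutate(r$spots, room = r$session$room, date = r$session$date)
  }))
  slong <- tidyr::pivot_longer(spots, c("random_x_mm", "random_y_mm"),
                               names_to = "axis", values_to = "mm")
  slong$axis <- ifelse(grepl("_x_", slong$axis), "Random X", "Random Y")
  both <- bind_rows(long[c("room", "axis", "mm")], slong[c("room", "axis", "mm")])
  ggplot2::ggplot(both, ggplot2::aes(x = .data$room, y = .data$mm)) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dashed", colour = "red") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = "Room", y = "Position error (mm)")
}

#' @method autoplot dose_grid
#' @export
autoplot.dose_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    (if (object$signed) {
      ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red")
    } else {
      ggplot2::scale_fill_viridis_c()
    }) +
    ggplot2::labs(x = "X (mm)", y = "Y (mm)",
                  fill = if (object$signed) "Dose diff" else "Dose")
}

#' @method autoplot gamma_result
#' @export
autoplot.gamma_result <- function(object, ...) {
  grid <- dose_grid(ifelse(is.na(object$gamma), 0, object$gamma),
                    object$origin_mm, object$spacing_mm, signed = TRUE)
  df <- as_tibble(grid)
  df$value[is.na(as.vector(object$gamma))] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", limits = c(0, NA)) +
    ggplot2::labs(x = "X (mm)", y = "Y (mm)", fill = "gamma",
                  title = sprintf("Gamma %g%%/%g mm: pass rate %.1f%%",
                                  object$criteria$dose_percent,
                                  object$criteria$dta_mm, object$pass_rate))
}
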