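# Tabular spot containers.
#
# A *plan* is a tibble with one row per planned spot:
#   field_id, gantry_angle_deg, layer_index, energy_MeV, spot_index,
#   x_mm, y_mm, mu
# A *delivery session* is a tibble with one row per delivered spot:
#   session_id, room, date, field_id, gantry_angle_deg, layer_index,
#   energy_MeV, spot_index, x_mm, y_mm, mu, sigma_x_mm, sigma_y_mm
#
# Positions are lateral X/Y at isocenter (IEC 61217, mm); MU is absolute
# monitor units; sizes are one-sigma of the 2D Gaussian spot per axis (mm).
# Layer indices are 0-based and contiguous within a field.

PLAN_COLS <- c("field_id", "gantry_angle_deg", "layer_index", "energy_MeV",
               "spot_index", "x_mm", "y_mm", "mu")
LOG_COLS <- c("session_id", "room", "date", "field_id", "gantry_angle_deg",
              "layer_index", "energy_MeV", "spot_index", "x_mm", "y_mm",
              "mu", "sigma_x_mm", "sigma_y_mm")

# deliverable energy band of the modelled synchrotron (MeV)
ENERGY_MIN <- 69.4
ENERGY_MAX <- 221.3

#' The machine's discrete energy levels
#'
#' The modelled delivery system provides 96 discrete proton energies evenly
#' spaced over 69.4-221.3 MeV, each printed to 0.1 MeV.
#'
#' @return Numeric vector of 96 energies (MeV), ascending.
#' @export
proton_energy_levels <- function() {
  round(seq(ENERGY_MIN, ENERGY_MAX, length.out = 96), 1)
}

check_spot_frame <- function(x, cols, what) {
  if (!is.data.frame(x)) {
    qa_abort(paste0(what, " must be a data frame"), "qa_domain_error")
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    qa_abort(paste0(what, " is missing columns: ", paste(missing, collapse = ", ")),
             "qa_domain_error")
  }
  invisible(x)
}

check_plan_frame <- function(x, what = "plan") check_spot_frame(x, PLAN_COLS, what)
check_log_frame <- function(x, what = "session") check_spot_frame(x, LOG_COLS, what)

#' Validate spots against deliverability limits
#'
#' Checks each spot's MU against the deliverable band
#' `[mu_min, mu_max]` and its layer energy against the machine's 69.4-221.3
#' MeV range, plus finiteness of positions. Violations are returned as
#' data, one row per failed rule, never raised as errors.
#'
#' @param spots A plan or session tibble (any frame with `energy_MeV`,
#'   `x_mm`, `y_mm`, `mu` columns).
#' @param config A [tolerance_config()].
#' @return A tibble with columns `row`, `rule`, `value`, `limit`; zero rows
#'   when every spot is valid.
#' @export
validate_spots <- function(spots, config = tolerance_config()) {
  check_spot_frame(spots, c("energy_MeV", "x_mm", "y_mm", "mu"), "spots")
  stopifnot(inherits(config, "tolerance_config"))
  viol <- function(idx, rule, value, limit) {
    tibble(row = idx, rule = rule, value = value, limit = limit)
  }
  out <- list(
    viol(which(spots$mu < config$mu_min), "mu_below_min",
         spots$mu[spots$mu < config$mu_min], config$mu_min),
    viol(which(spots$mu > config$mu_max), "mu_above_max",
         spots$mu[spots$mu > config$mu_max], config$mu_max),
    viol(which(spots$energy_MeV < ENERGY_MIN), "energy_below_min",
         spots$energy_MeV[spots$energy_MeV < ENERGY_MIN], ENERGY_MIN),
    viol(which(spots$energy_MeV > ENERGY_MAX), "energy_above_max",
         spots$energy_MeV[spots$energy_MeV > ENERGY_MAX], ENERGY_MAX),
    viol(which(!is.finite(spots$x_mm)), "x_not_finite",
         spots$x_mm[!is.finite(spots$x_mm)], NA_real_),
    viol(which(!is.finite(spots$y_mm)), "y_not_finite",
         spots$y_mm[!is.finite(spots$y_mm)], NA_real_)
  )
  dplyr::arrange(dplyr::bind_rows(out), .data$row, .data$rule)
}
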