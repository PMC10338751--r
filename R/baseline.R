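# Commissioning spot-size baseline.
#
# During commissioning the spot position monitor records the accepted spot
# size (one-sigma per axis, mm) for each combination of energy level and
# gantry angle; delivered layer sizes are later checked against this table.
# Lookup interpolates linearly in energy between bracketing entries (the
# energy grid is dense: 96 levels) and takes the nearest tabulated gantry
# angle (the commissioning angle grid is coarse).

#' Construct a spot-size baseline
#'
#' @param entries Tibble with columns `energy_MeV`, `gantry_angle_deg`,
#'   `sigma_x_mm`, `sigma_y_mm`. Keys (energy, angle) must be unique and
#'   sigmas strictly positive.
#' @return A `size_baseline` object.
#' @export
size_baseline <- function(entries) {
  check_spot_frame(entries, c("energy_MeV", "gantry_angle_deg",
                              "sigma_x_mm", "sigma_y_mm"), "baseline")
  entries <- as_tibble(entries)
  if (any(entries$sigma_x_mm <= 0) || any(entries$sigma_y_mm <= 0)) {
    qa_abort("baseline sigmas must be strictly positive", "qa_format_error")
  }
  key <- paste(entries$energy_MeV, entries$gantry_angle_deg)
  if (anyDuplicated(key)) {
    qa_abort("duplicate (energy, gantry angle) baseline entries", "qa_format_error")
  }
  cols <- c("energy_MeV", "gantry_angle_deg", "sigma_x_mm", "sigma_y_mm")
  structure(list(entries = dplyr::arrange(entries[cols], .data$gantry_angle_deg,
                                          .data$energy_MeV)),
            class = "size_baseline")
}

#' Look up baseline spot sigmas
#'
#' Linear interpolation in energy between the bracketing table entries at
#' the nearest tabulated gantry angle.
#'
#' @param baseline A [size_baseline()].
#' @param energy_MeV Energy of the layer (MeV); must lie within the
#'   tabulated energy span of the selected angle.
#' @param gantry_angle_deg Gantry angle (degrees).
#' @return Named numeric vector `c(sigma_x_mm = , sigma_y_mm = )`.
#' @export
baseline_sigma <- function(baseline, energy_MeV, gantry_angle_deg) {
  stopifnot(inherits(baseline, "size_baseline"))
  tab <- baseline$entries
  angles <- sort(unique(tab$gantry_angle_deg))
  # nearest neighbour on the angle circle
  circ <- pmin(abs(angles - gantry_angle_deg %% 360),
               360 - abs(angles - gantry_angle_deg %% 360))
  ang <- angles[which.min(circ)]
  tab <- tab[tab$gantry_angle_deg == ang, ]
  if (energy_MeV < min(tab$energy_MeV) || energy_MeV > max(tab$energy_MeV)) {
    qa_abort(sprintf("baseline lookup: energy %.1f MeV outside tabulated span [%.1f, %.1f] at angle %g",
                     energy_MeV, min(tab$energy_MeV), max(tab$energy_MeV), ang),
             "qa_config_error")
  }
  c(
    sigma_x_mm = stats::approx(tab$energy_MeV, tab$sigma_x_mm, xout = energy_MeV)$y,
    sigma_y_mm = stats::approx(tab$energy_MeV, tab$sigma_y_mm, xout = energy_MeV)$y
  )
}

#' Synthetic commissioning baseline
#'
#' A stand-in commissioning table for simulation and testing: smooth,
#' slowly decreasing monitor-plane spot sigmas over the 96 machine energy
#' levels, around 9-13 mm. The scale is chosen so that the +/-10 percent
#' size tolerance corresponds to roughly +/-1 mm, matching how those two
#' bounds relate on the modelled system. A small fixed X/Y asymmetry and a
#' mild gantry-angle dependence emulate steering-magnet effects.
#'
#' @param gantry_angles_deg Commissioning angle grid. Default
#'   `c(0, 90, 180, 270)`.
#' @return A `size_baseline` object covering all 96 energy levels.
#' @export
synthetic_size_baseline <- function(gantry_angles_deg = c(0, 90, 180, 270)) {
  ee <- proton_energy_levels()
  grid <- tidyr::expand_grid(gantry_angle_deg = gantry_angles_deg, energy_MeV = ee)
  grid <- mutate(
    grid,
    sigma_x_mm = 7.0 + 420 / .data$energy_MeV +
      0.12 * cos(pi * .data$gantry_angle_deg / 180),
    sigma_y_mm = 7.4 + 400 / .data$energy_MeV +
      0.12 * sin(pi * .data$gantry_angle_deg / 180) ^ 2
  )
  size_baseline(grid)
}

#' Read / write a spot-size baseline CSV
#'
#' CSV header: `energy_MeV,gantry_angle_deg,sigma_x_mm,sigma_y_mm`.
#' Duplicate keys and non-positive sigmas are format errors.
#'
#' @param path File path.
#' @return `read_size_baseline`: a `size_baseline`.
#' @export
read_size_baseline <- function(path) {
  if (!file.exists(path)) qa_abort(paste0("no such file: ", path), "qa_io_error")
  tab <- read_strict_csv(path, c("energy_MeV", "gantry_angle_deg",
                                 "sigma_x_mm", "sigma_y_mm"))
  size_baseline(tab)
}

#' @rdname read_size_baseline
#' @param baseline A `size_baseline` to serialize.
#' @export
write_size_baseline <- function(baseline, path) {
  stopifnot(inherits(baseline, "size_baseline"))
  cols <- c("energy_MeV", "gantry_angle_deg", "sigma_x_mm", "sigma_y_mm")
  write_dialect_csv(baseline$entries[cols], path)
  invisible(path)
}

#' @export
print.size_baseline <- function(x, ...) {
  cat(sprintf("<size_baseline> %d entries, %d gantry angle(s), energies %.1f-%.1f MeV\n",
              nrow(x$entries), length(unique(x$entries$gantry_angle_deg)),
              min(x$entries$energy_MeV), max(x$entries$energy_MeV)))
  invisible(x)
}
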