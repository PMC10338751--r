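# Fixtures are built in code: tiny hand-sized plans plus converters that
# present a plan as its own (identity) delivery.

tiny_plan <- function(n_layers = 3, n_spots = 5, field_id = "F01",
                      gantry = 0, energies = NULL) {
  if (is.null(energies)) energies <- rev(proton_energy_levels()[seq_len(n_layers) * 10])
  purrr::list_rbind(lapply(seq_len(n_layers), function(li) {
    tibble::tibble(
      field_id = field_id,
      gantry_angle_deg = gantry,
      layer_index = li - 1,
      energy_MeV = energies[li],
      spot_index = seq_len(n_spots) - 1,
      x_mm = seq(-10, 10, length.out = n_spots) + (li - 1),
      y_mm = rep(2 * (li - 1), n_spots),
      mu = rep(0.010, n_spots)
    )
  }))
}

# identity delivery: delivered == planned, sizes straight off the baseline
plan_as_session <- function(plan, baseline = synthetic_size_baseline(),
                            session_id = "S-IDENT", room = "G1",
                            date = "2021-01-15") {
  sig <- t(vapply(seq_len(nrow(plan)), function(i) {
    baseline_sigma(baseline, plan$energy_MeV[i], plan$gantry_angle_deg[i])
  }, numeric(2)))
  tibble::tibble(
    session_id = session_id, room = room, date = date,
    field_id = plan$field_id, gantry_angle_deg = plan$gantry_angle_deg,
    layer_index = plan$layer_index, energy_MeV = plan$energy_MeV,
    spot_index = plan$spot_index, x_mm = plan$x_mm, y_mm = plan$y_mm,
    mu = plan$mu, sigma_x_mm = sig[, 1], sigma_y_mm = sig[, 2]
  )
}

flat_baseline <- function(sigma_x = 5, sigma_y = 5, angles = 0) {
  size_baseline(tidyr::expand_grid(
    gantry_angle_deg = angles, energy_MeV = proton_energy_levels()
  ) |> dplyr::mutate(sigma_x_mm = sigma_x, sigma_y_mm = sigma_y))
}

expect_qa_error <- function(expr, class, pattern = NULL) {
  err <- testthat::expect_error(expr, class = class)
  if (!is.null(pattern)) testthat::expect_match(conditionMessage(err), pattern)
  invisible(err)
}
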