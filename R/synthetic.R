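# Synthetic plan generation and delivery simulation with known ground
# truth.
#
# The generator emulates the fleet characteristics of the modelled
# machine: 96 discrete energies on 69.4-221.3 MeV with layer energies
# clustered around 114.4 +/- 26.4 MeV, spots on a jittered rectangular
# grid, and spot MU drawn from a lognormal moment-matched to mean 0.010
# and SD 0.009 MU then clipped to the deliverable band [0.003, 1.015] MU
# (the lognormal captures the hard minimum and right skew of clinical MU
# histograms). Delivery perturbs the plan with the exact generative
# inverse of the QA decomposition: one systematic shift per layer and
# axis, plus independent per-spot jitter and MU noise, plus one size
# deviation per layer and axis relative to the commissioning baseline.
# Every draw is recorded in the ground-truth object.
#
# All randomness flows from the seed argument via a locally scoped RNG
# (the global random state is left untouched); with seed = NULL the
# current RNG state is used.

with_local_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Delivery error model
#'
#' Defaults are the fleet-level SDs observed on the modelled system:
#' per-layer systematic position SDs 0.189/0.175 mm (X/Y), per-spot random
#' position SDs 0.049/0.044 mm, per-spot MU noise SD 2.0e-4 MU and
#' per-layer size deviation SDs 0.131/0.166 mm. Mean systematic offsets
#' default to zero; a constant machine bias can be injected through
#' `sys_mean_x_mm`/`sys_mean_y_mm`.
#'
#' @param sys_sd_x_mm,sys_sd_y_mm SD of per-layer systematic shifts (mm).
#' @param rand_sd_x_mm,rand_sd_y_mm SD of per-spot position jitter (mm).
#' @param mu_sd SD of per-spot MU noise (MU).
#' @param size_sd_x_mm,size_sd_y_mm SD of per-layer size deviations (mm).
#' @param sys_mean_x_mm,sys_mean_y_mm Mean systematic shift (mm).
#' @param seed Integer seed for [simulate_delivery()], or `NULL`.
#' @return An `error_model` object.
#' @export
error_model <- function(sys_sd_x_mm = 0.189, sys_sd_y_mm = 0.175,
                        rand_sd_x_mm = 0.049, rand_sd_y_mm = 0.044,
                        mu_sd = 2.0e-4,
                        size_sd_x_mm = 0.131, size_sd_y_mm = 0.166,
                        sys_mean_x_mm = 0, sys_mean_y_mm = 0,
                        seed = NULL) {
  m <- list(sys_sd_x_mm = sys_sd_x_mm, sys_sd_y_mm = sys_sd_y_mm,
            rand_sd_x_mm = rand_sd_x_mm, rand_sd_y_mm = rand_sd_y_mm,
            mu_sd = mu_sd, size_sd_x_mm = size_sd_x_mm,
            size_sd_y_mm = size_sd_y_mm,
            sys_mean_x_mm = sys_mean_x_mm, sys_mean_y_mm = sys_mean_y_mm,
            seed = seed)
  sds <- m[grepl("_sd", names(m))]
  if (any(vapply(sds, function(v) !is.numeric(v) || v < 0, logical(1)))) {
    qa_abort("error model SDs must be non-negative numbers", "qa_domain_error")
  }
  structure(m, class = "error_model")
}

# lognormal parameters moment-matched to mean m, sd s
lognormal_params <- function(m, s) {
  if (m <= 0 || s <= 0) qa_abort("MU distribution needs positive mean and SD", "qa_domain_error")
  sdlog <- sqrt(log(1 + (s / m)^2))
  c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic treatment plan
#'
#' @param n_fields Number of fields. Default 2.
#' @param layers_per_field Energy layers per field. Default 10.
#' @param spots_per_layer Spots per layer. Default 30.
#' @param energy_mean_MeV,energy_sd_MeV Normal distribution from which
#'   layer energies are drawn before snapping to the machine's 96 levels.
#'   Defaults 114.4 and 26.4 MeV.
#' @param mu_mean,mu_sd Target mean and SD of the spot MU lognormal.
#'   Defaults 0.010 and 0.009 MU.
#' @param mu_range Deliverable clip band for spot MU. Default
#'   `c(0.003, 1.015)` MU.
#' @param spot_spacing_mm Nominal grid pitch of spot positions. Default 6.
#' @param seed Integer seed; identical seeds give identical plans.
#' @return A plan tibble.
#' @export
generate_plan <- function(n_fields = 2, layers_per_field = 10,
                          spots_per_layer = 30,
                          energy_mean_MeV = 114.4, energy_sd_MeV = 26.4,
                          mu_mean = 0.010, mu_sd = 0.009,
                          mu_range = c(0.003, 1.015),
                          spot_spacing_mm = 6, seed = NULL) {
  if (n_fields < 1 || layers_per_field < 1 || spots_per_layer < 1) {
    qa_abort("all counts must be >= 1", "qa_domain_error")
  }
  if (layers_per_field > 96) {
    qa_abort("layers_per_field cannot exceed the 96 machine energy levels",
             "qa_domain_error")
  }
  lp <- lognormal_params(mu_mean, mu_sd)
  levels <- proton_energy_levels()
  with_local_seed(seed, {
    list_rbind(lapply(seq_len(n_fields), function(fi) {
      # layer energies: clinical-like normal snapped to machine levels,
      # unique within the field, delivered high to low
      draws <- rnorm(4 * layers_per_field, energy_mean_MeV, energy_sd_MeV)
      draws <- pmin(pmax(draws, ENERGY_MIN), ENERGY_MAX)
      idx <- unique(vapply(draws, function(e) which.min(abs(levels - e)), integer(1)))
      while (length(idx) < layers_per_field) {
        idx <- unique(c(idx, sample.int(length(levels), 1)))
      }
      energies <- sort(levels[idx[seq_len(layers_per_field)]], decreasing = TRUE)
      angle <- sample(seq(0, 350, by = 10), 1)
      list_rbind(lapply(seq_len(layers_per_field), function(li) {
        n_side <- ceiling(sqrt(spots_per_layer))
        gx <- rep(seq_len(n_side), times = n_side)[seq_len(spots_per_layer)]
        gy <- rep(seq_len(n_side), each = n_side)[seq_len(spots_per_layer)]
        ctr <- (n_side + 1) / 2
        tibble(
          field_id = sprintf("F%02d", fi),
          gantry_angle_deg = angle,
          layer_index = li - 1,
          energy_MeV = energies[li],
          spot_index = seq_len(spots_per_layer) - 1,
          x_mm = round((gx - ctr) * spot_spacing_mm +
                         runif(spots_per_layer, -1, 1), 3),
          y_mm = round((gy - ctr) * spot_spacing_mm +
                         runif(spots_per_layer, -1, 1), 3),
          mu = pmin(pmax(rlnorm(spots_per_layer, lp["meanlog"], lp["sdlog"]),
                         mu_range[1]), mu_range[2])
        )
      }))
    }))
  })
}

#' Simulate a delivery with known injected errors
#'
#' Perturbs a plan with the generative inverse of the QA decomposition:
#' per-layer systematic shifts, per-spot jitter and MU noise, and
#' per-layer size deviations about the commissioning baseline. Every
#' draw is returned as ground truth so estimator recovery can be checked
#' exactly.
#'
#' @param plan Plan tibble from [generate_plan()] or [read_plan()].
#' @param model An [error_model()]; its `seed` drives all randomness.
#' @param baseline A [size_baseline()] supplying delivered sizes. Default
#'   [synthetic_size_baseline()].
#' @param session_id,room,date Session metadata recorded in the log.
#' @return List with `session` (session tibble) and `truth` (list of
#'   `layers` and `spots` tibbles holding the injected draws).
#' @export
simulate_delivery <- function(plan, model = error_model(),
                              baseline = synthetic_size_baseline(),
                              session_id = "SIM-001", room = "G1",
                              date = "2021-06-15") {
  check_plan_frame(plan)
  stopifnot(inherits(model, "error_model"))
  if (!room %in% QA_ROOMS) {
    qa_abort(paste0("room must be one of ", paste(QA_ROOMS, collapse = "/")),
             "qa_domain_error")
  }
  plan <- order_plan(as_tibble(plan))
  with_local_seed(model$seed, {
    layer_key <- paste(plan$field_id, plan$layer_index)
    layers <- plan[!duplicated(layer_key), c("field_id", "gantry_angle_deg",
                                             "layer_index", "energy_MeV")]
    nl <- nrow(layers)
    truth_layers <- mutate(
      layers,
      shift_x_mm = rnorm(nl, model$sys_mean_x_mm, model$sys_sd_x_mm),
      shift_y_mm = rnorm(nl, model$sys_mean_y_mm, model$sys_sd_y_mm),
      size_dev_x_mm = rnorm(nl, 0, model$size_sd_x_mm),
      size_dev_y_mm = rnorm(nl, 0, model$size_sd_y_mm)
    )
    base <- t(vapply(seq_len(nl), function(i) {
      baseline_sigma(baseline, layers$energy_MeV[i], layers$gantry_angle_deg[i])
    }, numeric(2)))
    truth_layers$baseline_sigma_x_mm <- base[, 1]
    truth_layers$baseline_sigma_y_mm <- base[, 2]

    ns <- nrow(plan)
    truth_spots <- tibble(
      field_id = plan$field_id, layer_index = plan$layer_index,
      spot_index = plan$spot_index,
      jitter_x_mm = rnorm(ns, 0, model$rand_sd_x_mm),
      jitter_y_mm = rnorm(ns, 0, model$rand_sd_y_mm),
      mu_noise = rnorm(ns, 0, model$mu_sd)
    )

    li <- match(layer_key, paste(truth_layers$field_id, truth_layers$layer_index))
    session <- tibble(
      session_id = session_id, room = room, date = date,
      field_id = plan$field_id,
      gantry_angle_deg = plan$gantry_angle_deg,
      layer_index = plan$layer_index,
      energy_MeV = plan$energy_MeV,
      spot_index = plan$spot_index,
      x_mm = round(plan$x_mm + truth_layers$shift_x_mm[li] + truth_spots$jitter_x_mm, 3),
      y_mm = round(plan$y_mm + truth_layers$shift_y_mm[li] + truth_spots$jitter_y_mm, 3),
      mu = pmax(plan$mu + truth_spots$mu_noise, 0),
      sigma_x_mm = truth_layers$baseline_sigma_x_mm[li] + truth_layers$size_dev_x_mm[li],
      sigma_y_mm = truth_layers$baseline_sigma_y_mm[li] + truth_layers$size_dev_y_mm[li]
    )
    list(session = session, truth = list(layers = truth_layers, spots = truth_spots))
  })
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element returned by [simulate_delivery()].
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
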