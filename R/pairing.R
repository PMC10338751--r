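# Plan-to-delivery spot pairing.
#
# Layers are matched by layer_index with an exact match required on the
# nominal energy (both sides print it to 0.1 MeV and originate from the
# same layer definition, so no tolerance applies). Within a layer spots
# are matched by delivery order. A beam hold can split one planned spot
# across two consecutive log rows at the same position (delivery resumes
# with the remaining MU); when the delivered layer has more rows than the
# planned one, consecutive rows whose positions agree within 0.01 mm are
# merged (MU summed, sizes MU-weighted) before pairing. Nearest-neighbour
# matching is deliberately not used: it can silently mask gross positional
# errors.

MERGE_POS_TOL_MM <- 0.01

merge_resumed_spots <- function(layer) {
  if (nrow(layer) < 2) return(layer)
  grp <- cumsum(c(TRUE, !(abs(diff(layer$x_mm)) <= MERGE_POS_TOL_MM &
                            abs(diff(layer$y_mm)) <= MERGE_POS_TOL_MM)))
  if (max(grp) == nrow(layer)) return(layer)
  has_sigma <- "sigma_x_mm" %in% names(layer)
  merged <- layer[!duplicated(grp), , drop = FALSE]
  merged$mu <- as.numeric(tapply(layer$mu, grp, sum))
  if (has_sigma) {
    wmean <- function(v, w) if (all(is.na(v))) NA_real_ else stats::weighted.mean(v, w, na.rm = TRUE)
    idx <- split(seq_len(nrow(layer)), grp)
    merged$sigma_x_mm <- unname(vapply(idx, function(i) wmean(layer$sigma_x_mm[i], layer$mu[i]), numeric(1)))
    merged$sigma_y_mm <- unname(vapply(idx, function(i) wmean(layer$sigma_y_mm[i], layer$mu[i]), numeric(1)))
  }
  merged
}

pair_one_layer <- function(p_layer, d_layer, field_id, layer_index) {
  if (nrow(d_layer) > nrow(p_layer)) d_layer <- merge_resumed_spots(d_layer)
  if (nrow(d_layer) != nrow(p_layer)) {
    qa_abort(sprintf("field %s layer %d: %d planned vs %d delivered spots (after merging resumed rows)",
                     field_id, layer_index, nrow(p_layer), nrow(d_layer)),
             "qa_pairing_error")
  }
  tibble(
    field_id = field_id,
    gantry_angle_deg = p_layer$gantry_angle_deg,
    layer_index = layer_index,
    energy_MeV = p_layer$energy_MeV,
    spot_index = p_layer$spot_index,
    x_plan = p_layer$x_mm, y_plan = p_layer$y_mm, mu_plan = p_layer$mu,
    x_del = d_layer$x_mm, y_del = d_layer$y_mm, mu_del = d_layer$mu,
    sigma_x_mm = if ("sigma_x_mm" %in% names(d_layer)) d_layer$sigma_x_mm else NA_real_,
    sigma_y_mm = if ("sigma_y_mm" %in% names(d_layer)) d_layer$sigma_y_mm else NA_real_
  )
}

#' Pair planned and delivered spots
#'
#' Matches each planned spot of a field with the corresponding delivered
#' spot: layers by index with an exact energy match, spots within a layer
#' by delivery order after merging beam-hold resumption rows. Returns
#' exactly one row per planned spot.
#'
#' @param plan Plan tibble (one or more fields).
#' @param delivered Delivered spots: a session tibble or plan-shaped
#'   tibble covering the same `field_id`s.
#' @return Tibble with one row per planned spot: keys plus `x_plan`,
#'   `y_plan`, `mu_plan`, `x_del`, `y_del`, `mu_del`, `sigma_x_mm`,
#'   `sigma_y_mm`.
#' @export
pair_spots <- function(plan, delivered) {
  check_plan_frame(plan)
  check_spot_frame(delivered, PLAN_COLS, "delivered")
  if (nrow(plan) == 0 || nrow(delivered) == 0) {
    qa_abort("plan and delivery must be non-empty", "qa_pairing_error")
  }
  plan <- order_plan(as_tibble(plan))
  out <- lapply(unique(plan$field_id), function(fid) {
    p_field <- plan[plan$field_id == fid, ]
    d_field <- delivered[delivered$field_id == fid, ]
    if (nrow(d_field) == 0) {
      qa_abort(paste0("no delivered spots for field ", fid), "qa_pairing_error")
    }
    p_layers <- sort(unique(p_field$layer_index))
    d_layers <- sort(unique(d_field$layer_index))
    if (!identical(as.numeric(p_layers), as.numeric(d_layers))) {
      qa_abort(sprintf("field %s: %d planned vs %d delivered layers",
                       fid, length(p_layers), length(d_layers)), "qa_pairing_error")
    }
    list_rbind(lapply(p_layers, function(li) {
      p_layer <- p_field[p_field$layer_index == li, ]
      d_layer <- d_field[d_field$layer_index == li, ]
      # energy identity is exact on the nominal value printed to 0.1 MeV
      e_p <- sprintf("%.1f", p_layer$energy_MeV[1])
      e_d <- sprintf("%.1f", d_layer$energy_MeV[1])
      if (!identical(e_p, e_d)) {
        qa_abort(sprintf("field %s layer %d: planned energy %s != delivered %s MeV",
                         fid, li, e_p, e_d), "qa_pairing_error")
      }
      pair_one_layer(p_layer, d_layer, fid, li)
    }))
  })
  list_rbind(out)
}
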