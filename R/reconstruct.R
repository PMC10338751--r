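# Delivered-plan reconstruction.
#
# The reconstructed plan is the original plan with each spot's position
# and MU replaced by the delivered values from the log, so the delivered
# dose can be recomputed and compared against the intended one.

#' Reconstruct the delivered plan from a delivery log
#'
#' Substitutes delivered positions and MU for the planned values of every
#' matched spot; structure, energies and spot order stay those of the
#' plan.
#'
#' @param plan Plan tibble.
#' @param session Session tibble covering the plan's fields.
#' @return A plan tibble with delivered `x_mm`, `y_mm`, `mu`.
#' @export
reconstruct_plan <- function(plan, session) {
  paired <- pair_spots(plan, session)
  tibble(
    field_id = paired$field_id,
    gantry_angle_deg = paired$gantry_angle_deg,
    layer_index = paired$layer_index,
    energy_MeV = paired$energy_MeV,
    spot_index = paired$spot_index,
    x_mm = paired$x_del,
    y_mm = paired$y_del,
    mu = paired$mu_del
  )
}

#' Write the reconstructed (delivered) plan
#'
#' Pairs every field of the plan with the session, substitutes delivered
#' positions and MU, embeds a provenance note (session id and tool
#' version) and writes the result in the requested plan format; the
#' output is re-readable by [read_plan()].
#'
#' @param plan Plan tibble.
#' @param session Session tibble.
#' @param path Output path.
#' @param format `"csv"` or `"rtion-dicom"`.
#' @return The reconstructed plan tibble, invisibly.
#' @export
write_reconstructed_plan <- function(plan, session, path,
                                     format = c("csv", "rtion-dicom")) {
  format <- match.arg(format)
  recon <- reconstruct_plan(plan, session)
  note <- sprintf("reconstructed from session %s by spotqa %s",
                  session$session_id[1], utils::packageVersion("spotqa"))
  write_plan(recon, path, format = format, comment = note)
  invisible(recon)
}
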