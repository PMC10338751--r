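# Proton range-energy conversion against an embedded CSDA reference table.
#
# The table holds continuous-slowing-down-approximation (CSDA) ranges of
# protons in liquid water (g/cm^2; numerically equal to cm at unit density)
# at standard reference energies. Between tabulated energies the range is
# interpolated with a local power law R = a * E^p through the bracketing
# entries (linear in log-log space), the conventional way range tables are
# interpolated: the Bragg-Kleeman exponent p drifts from ~1.73 to ~1.80
# across the clinical domain, so a single global power law is biased at the
# few-percent level while the piecewise form is exact at the nodes.

csda_water_table <- function() {
  path <- system.file("extdata", "proton_water_csda_range.csv",
                      package = "spotqa", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  tibble::as_tibble(tab)
}

# fitted domain: clinical energies plus margin, inside the tabulated support
RANGE_E_MIN <- 60
RANGE_E_MAX <- 230

#' Convert proton energy to water-equivalent range
#'
#' Converts nominal beam energy to the CSDA range in liquid water by
#' piecewise power-law (log-log linear) interpolation of an embedded
#' reference range table. At unit density the returned value in cm equals
#' the tabulated mass range in g/cm^2.
#'
#' @param energy_MeV Numeric vector of proton energies in MeV. Must lie in
#'   \[60, 230\] MeV, the validated domain of the fit.
#' @return Numeric vector of water-equivalent ranges in cm, strictly
#'   increasing in energy.
#' @examples
#' energy_to_water_range(114.4) # ~9.8 cm
#' @export
energy_to_water_range <- function(energy_MeV) {
  if (!is.numeric(energy_MeV) || anyNA(energy_MeV)) {
    qa_abort("`energy_MeV` must be numeric and non-missing.", "qa_domain_error")
  }
  if (any(energy_MeV < RANGE_E_MIN | energy_MeV > RANGE_E_MAX)) {
    qa_abort(
      sprintf("energy outside the fitted domain [%g, %g] MeV", RANGE_E_MIN, RANGE_E_MAX),
      "qa_domain_error"
    )
  }
  tab <- csda_water_table()
  out <- stats::approx(log(tab$energy_MeV), log(tab$csda_range_g_cm2),
                       xout = log(energy_MeV), method = "linear")$y
  exp(out)
}
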