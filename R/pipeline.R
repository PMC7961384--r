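#' Full REES analysis pipeline
#'
#' The standard workflow for an observed REES dataset: fit the Boltzmann
#' sigmoid, calibrate the ligand photophysics from the sigmoid endpoints
#' and the absorption maximum, scan candidate free-energy landscapes, and
#' assemble the landscape report for the winning model.
#'
#' @param data a \code{\link{rees_dataset}}.
#' @param abs_max absorption maximum of the ligand; interpreted as nm if
#'   greater than 100, eV otherwise.
#' @param m_range candidate microstate counts.
#' @param b_values candidate landscape exponents, or \code{"free"}.
#' @param cfg a \code{\link{model_config}}.
#' @param criterion model-selection criterion, \code{"slsq"} or
#'   \code{"aic"}.
#' @param target fit candidates to the \code{"sigmoid"} representation
#'   (default, the standard treatment of noisy experimental data) or to the
#'   raw \code{"data"} points.
#' @param kd optional dissociation/inhibition constant (molar) enabling the
#'   binding decomposition: intrusion is the negated landscape span and
#'   association the remainder of the total binding free energy.
#' @return A list with \code{sigmoid}, \code{ligand}, \code{comparison},
#'   \code{best} (the winning \code{fel_fit}), \code{landscape} and, when
#'   \code{kd} is given, \code{binding}.
#' @examples
#' \donttest{
#' fx <- make_reference_fixtures()
#' res <- analyze_rees(fx$p38a$dataset, abs_max = fx$p38a$abs_max_ev,
#'                     m_range = 9:11, target = "data")
#' res$landscape
#' }
#' @export
analyze_rees <- function(data, abs_max, m_range = 3:20, b_values = 2,
                         cfg = model_config(),
                         criterion = c("slsq", "aic"),
                         target = c("sigmoid", "data"), kd = NULL) {
  criterion <- match.arg(criterion)
  target <- match.arg(target)
  abs_max_ev <- if (abs_max > 100) wavelength_to_energy(abs_max) else abs_max
  sig <- fit_sigmoid(data)
  ep <- endpoints_from_sigmoid(sig)
  lig <- ligand_from_spectra(abs_max_ev, ep[["em_blue"]], ep[["em_red"]],
                             kappa = cfg$kappa)
  cmp <- scan_models(if (target == "sigmoid") sig else data, lig,
                     m_range = m_range, b_values = b_values, cfg = cfg,
                     eval_ex_nm = data$ex_nm, criterion = criterion)
  best <- best_model(cmp)
  out <- list(sigmoid = sig, ligand = lig, comparison = cmp, best = best,
              landscape = landscape_report(best$fel, cfg))
  if (!is.null(kd)) {
    tot <- kd_to_binding_energy(kd, cfg$temperature_K)
    intr <- -convert_energy(out$landscape$span_ev, "eV", "kcal/mol",
                            cfg$temperature_K)
    out$binding <- binding_decomposition(tot$kcal_mol, intr)
  }
  out
}
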