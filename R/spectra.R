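#' Convert photon energy to wavelength
#'
#' \code{lambda = hc / E} with \code{hc = 1239.84193} eV nm.
#'
#' @param e photon energy in eV (positive; vectorized).
#' @return Wavelength in nm.
#' @examples
#' energy_to_wavelength(2.950)  # ~420.3 nm
#' @export
energy_to_wavelength <- function(e) {
  if (any(!is.finite(e)) || any(e <= 0))
    stop("photon energy must be positive and finite")
  .hc_ev_nm / e
}

#' Convert wavelength to photon energy
#'
#' @param w wavelength in nm (positive; vectorized).
#' @return Photon energy in eV.
#' @export
wavelength_to_energy <- function(w) {
  if (any(!is.finite(w)) || any(w <= 0))
    stop("wavelength must be positive and finite")
  .hc_ev_nm / w
}

#' Simulate a theoretical REES curve
#'
#' Sweeps the collective coordinate over the configured grid and evaluates
#' the ensemble absorption and mean emission energies.  The resulting pairs
#' (excitation energy, emission energy) trace the red-edge excitation shift
#' curve; wavelength views are attached.  The excitation energy must be
#' strictly decreasing along x (it is, for positive \code{x_ct} in the
#' default mode), which makes the curve resamplable onto an arbitrary
#' excitation-wavelength grid.
#'
#' @param lig a \code{\link{ligand_photophysics}}.
#' @param fel a \code{\link{fel_spec}}.
#' @param cfg a \code{\link{model_config}}.
#' @param mode absorption-energy convention, see
#'   \code{\link{microstate_abs_energy}}.
#' @return An object of class \code{rees_curve}: a data frame with columns
#'   \code{x}, \code{ex_ev}, \code{em_ev}, \code{ex_nm}, \code{em_nm}.
#' @examples
#' lig <- ligand_photophysics(0.891, 3.347, 3.223)
#' fel <- fel_spec(0.00178, 2, 0.153, 10)
#' crv <- simulate_rees_curve(lig, fel)
#' summarize_curve(crv)
#' @export
simulate_rees_curve <- function(lig, fel, cfg = model_config(),
                                mode = c("printed", "strict")) {
  mode <- match.arg(mode)
  crv <- .ensemble_curve(lig, fel, cfg, mode = mode)
  if (is.null(crv))
    stop("ensemble excitation energy is not strictly decreasing along x; ",
         "review grid bounds or model parameters (x_ct must be positive)")
  out <- as.data.frame(crv)
  class(out) <- c("rees_curve", "data.frame")
  out
}

#' @export
print.rees_curve <- function(x, ...) {
  cat(sprintf("REES curve: %d points, excitation %.1f-%.1f nm, emission %.1f-%.1f nm\n",
              nrow(x), min(x$ex_nm), max(x$ex_nm), min(x$em_nm), max(x$em_nm)))
  invisible(x)
}

#' Summarize a REES curve
#'
#' Reports the asymptotic emission endpoints, the excitation wavelength at
#' which the emission reaches halfway between them (the transition
#' mid-point), and the slope d(em_nm)/d(ex_nm) at that mid-point.  The
#' mid-point is defined in emission space and mapped back to excitation
#' wavelength by monotone piecewise-linear interpolation.
#'
#' @param curve a \code{\link{simulate_rees_curve}} result (>= 3 points).
#' @param flat_tol emission span (nm) below which the curve is considered
#'   flat and the mid-point undefined.
#' @return An object of class \code{curve_summary} with fields
#'   \code{em_blue_nm}, \code{em_red_nm}, \code{midpoint_ex_nm},
#'   \code{midpoint_slope}, \code{midpoint_defined}.
#' @export
summarize_curve <- function(curve, flat_tol = 1e-6) {
  stopifnot(nrow(curve) >= 3)
  o <- order(curve$ex_nm)
  ex <- curve$ex_nm[o]
  em <- curve$em_nm[o]
  em_blue <- min(em[1], em[length(em)])
  em_red <- max(em[1], em[length(em)])
  if (em_red - em_blue < flat_tol) {
    return(structure(list(em_blue_nm = em_blue, em_red_nm = em_red,
                          midpoint_ex_nm = NA_real_,
                          midpoint_slope = NA_real_,
                          midpoint_defined = FALSE),
                     class = "curve_summary"))
  }
  em_mid <- (em_blue + em_red) / 2
  ## em is monotone in ex for case-(i) and case-(ii) landscapes; sort by
  ## emission so the interpolation works for both shift directions
  oe <- order(em)
  mid_ex <- stats::approx(em[oe], ex[oe], xout = em_mid,
                          ties = "ordered")$y
  j <- which.min(abs(ex - mid_ex))
  j <- min(max(j, 2L), length(ex) - 1L)
  slope <- (em[j + 1] - em[j - 1]) / (ex[j + 1] - ex[j - 1])
  structure(list(em_blue_nm = em_blue, em_red_nm = em_red,
                 midpoint_ex_nm = mid_ex, midpoint_slope = slope,
                 midpoint_defined = TRUE),
            class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat(sprintf("REES curve summary: emission %.1f -> %.1f nm\n",
              x$em_blue_nm, x$em_red_nm))
  if (x$midpoint_defined)
    cat(sprintf("  mid-point at excitation %.1f nm, slope %.3f nm/nm\n",
                x$midpoint_ex_nm, x$midpoint_slope))
  else cat("  flat curve: mid-point undefined\n")
  invisible(x)
}

#' Resample a REES curve onto an excitation-wavelength grid
#'
#' Monotone piecewise-linear interpolation of the model emission wavelength
#' at the requested excitation wavelengths.
#'
#' @param curve a \code{rees_curve}.
#' @param ex_nm excitation wavelengths (nm) within the curve's range.
#' @return Emission wavelengths (nm) at \code{ex_nm}.
#' @export
resample_curve <- function(curve, ex_nm) {
  rng <- range(curve$ex_nm)
  if (any(ex_nm < rng[1] | ex_nm > rng[2]))
    stop("requested excitation wavelengths fall outside the simulated ",
         "curve range [", round(rng[1], 1), ", ", round(rng[2], 1), "] nm")
  stats::approx(curve$ex_nm, curve$em_nm, xout = ex_nm, ties = "ordered")$y
}

#' Export a REES curve as CSV
#'
#' Two-column CSV (\code{excitation_nm,emission_nm}) with optional energy
#' columns, readable by \code{\link{read_rees_csv}}.
#'
#' @param curve a \code{rees_curve}.
#' @param path output file path.
#' @param energies include \code{ex_ev}/\code{em_ev} columns.
#' @return Invisibly, the path.
#' @export
write_curve_csv <- function(curve, path, energies = FALSE) {
  df <- data.frame(excitation_nm = curve$ex_nm, emission_nm = curve$em_nm)
  if (energies) {
    df$excitation_ev <- curve$ex_ev
    df$emission_ev <- curve$em_ev
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
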