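#' Ligand photophysics from spectral observables
#'
#' Fixes the three ligand parameters of the microstate model from three
#' experimental energies: the absorption maximum and the blue and red
#' asymptotic emission endpoints of the REES curve.  Half the Stokes shift
#' gives the reorganization energy, the mean of absorption and blue emission
#' gives the CT-GS gap of the most stable state, and the emission span gives
#' the gap of the least stable state:
#' \deqn{reorg = (abs - em_{blue})/2, \quad
#'       \Delta G_{CTGS0} = (abs + em_{blue})/2, \quad
#'       \Delta G_{CTGSN} = \Delta G_{CTGS0} - (em_{blue} - em_{red})}
#' and \eqn{x_{CT} = \sqrt{2\,reorg/\kappa}}.
#'
#' @param abs_max absorption-maximum energy (eV).
#' @param em_blue blue (short-wavelength) emission endpoint energy (eV).
#' @param em_red red (long-wavelength) emission endpoint energy (eV).
#' @param kappa curvature constant.
#' @return A \code{\link{ligand_photophysics}} object.
#' @examples
#' ligand_from_spectra(abs_max = 3.744, em_blue = 2.950, em_red = 2.826)
#' @export
ligand_from_spectra <- function(abs_max, em_blue, em_red, kappa = 1) {
  stopifnot(is.numeric(abs_max), is.numeric(em_blue), is.numeric(em_red),
            em_red > 0)
  if (em_blue > abs_max)
    stop("negative Stokes shift: blue emission endpoint (", em_blue,
         " eV) exceeds the absorption maximum (", abs_max, " eV)")
  if (em_red > em_blue)
    stop("red emission endpoint (", em_red,
         " eV) exceeds the blue endpoint (", em_blue, " eV)")
  reorg <- (abs_max - em_blue) / 2
  dg0 <- (abs_max + em_blue) / 2
  dgn <- dg0 - (em_blue - em_red)
  x_ct <- sqrt(2 * reorg / kappa)
  if (x_ct == 0) {
    ## zero Stokes shift: degenerate but well-defined (no CT displacement)
    warning("zero Stokes shift: x_ct = 0, the ligand would show no REES")
    return(structure(list(x_ct = 0, dg_ctgs0 = dg0, dg_ctgsn = dgn),
                     class = "ligand_photophysics"))
  }
  ligand_photophysics(x_ct = x_ct, dg_ctgs0 = dg0, dg_ctgsn = dgn,
                      kappa = kappa)
}

#' Emission endpoints from a fitted sigmoid
#'
#' Converts the two asymptotic emission wavelengths of a Boltzmann-sigmoid
#' fit to energies, blue endpoint first (shorter wavelength, higher energy).
#' If the fit's asymptotes arrive inverted they are reordered with a
#' warning; equal asymptotes (a flat, degenerate fit) are returned as equal
#' energies.
#'
#' @param sig a \code{\link{fit_sigmoid}} result.
#' @return Named numeric vector \code{c(em_blue = ..., em_red = ...)} in eV.
#' @export
endpoints_from_sigmoid <- function(sig) {
  blue_nm <- sig$em_blue_nm
  red_nm <- sig$em_red_nm
  if (blue_nm > red_nm) {
    warning("sigmoid asymptotes arrived red-first; reordering")
    tmp <- blue_nm; blue_nm <- red_nm; red_nm <- tmp
  }
  c(em_blue = wavelength_to_energy(blue_nm),
    em_red = wavelength_to_energy(red_nm))
}
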