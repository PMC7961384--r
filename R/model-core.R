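#' reesfel: protein-ligand free-energy landscapes from red-edge excitation
#' shift spectroscopy
#'
#' A two-level fluorescent ligand (ground state GS, charge-transfer excited
#' state CT) is distributed over a finite number of discrete protein-ligand
#' microstates, equally spaced along a collective coordinate x.  Absorption
#' and emission within each microstate follow classical Marcus theory on
#' harmonic free-energy surfaces; the microstate populations follow a
#' Boltzmann distribution over a parametric ground-state free-energy
#' landscape A*i^b.  Sweeping x produces the theoretical red-edge excitation
#' shift (REES) curve: mean emission energy as a function of ensemble
#' absorption energy.  Fitting this model to observed REES data recovers the
#' number of bound microstates, their energetics, and Marcus activation
#' barriers between them.
#'
#' @keywords internal
"_PACKAGE"

## Boltzmann constant in eV/K (CODATA exact value)
.kb_ev <- 8.617333262e-5

## hc in eV*nm for photon energy <-> wavelength conversion
.hc_ev_nm <- 1239.84193

#' Model configuration
#'
#' Global settings for the microstate model: the harmonic curvature constant
#' \eqn{\kappa} shared by all free-energy surfaces, the temperature, and the
#' sweep grid over the collective coordinate \eqn{x}.
#'
#' @param kappa curvature constant of the harmonic surfaces (energy per
#'   squared coordinate; with the dimensionless-coordinate convention
#'   \code{kappa = 1}, displacements carry units of eV^0.5).
#' @param temperature_K absolute temperature in kelvin.
#' @param x_min,x_max bounds of the collective-coordinate sweep (eV^0.5).
#' @param n_grid number of evenly spaced grid points on \code{[x_min, x_max]}.
#'
#' @return An object of class \code{model_config}.
#' @examples
#' cfg <- model_config()
#' cfg$kappa
#' @export
model_config <- function(kappa = 1, temperature_K = 298, x_min = -1,
                         x_max = 2, n_grid = 1001) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa > 0,
            is.numeric(temperature_K), length(temperature_K) == 1,
            temperature_K > 0,
            is.numeric(x_min), is.numeric(x_max), x_min < x_max,
            is.numeric(n_grid), n_grid >= 3)
  structure(list(kappa = kappa, temperature_K = temperature_K,
                 x_min = x_min, x_max = x_max, n_grid = as.integer(n_grid),
                 k_b = .kb_ev),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("Model configuration\n")
  cat(sprintf("  kappa: %g   T: %g K   kT: %.6f eV\n",
              x$kappa, x$temperature_K, x$k_b * x$temperature_K))
  cat(sprintf("  x grid: [%g, %g], %d points\n", x$x_min, x$x_max, x$n_grid))
  invisible(x)
}

#' Ligand photophysical parameters
#'
#' The three ligand quantities of the model: the displacement \code{x_ct} of
#' the CT-state surface along the collective coordinate, and the CT-GS
#' free-energy gaps of the most stable (\code{dg_ctgs0}) and least stable
#' (\code{dg_ctgsn}) microstates.  The ligand reorganization energy
#' \eqn{\kappa x_{CT}^2 / 2} is always recomputed from these, never stored
#' independently; see \code{\link{reorg_energy}}.
#'
#' @param x_ct CT-surface displacement (eV^0.5), must be positive.
#' @param dg_ctgs0 CT-GS gap of microstate 0 (eV).
#' @param dg_ctgsn CT-GS gap of the top microstate (eV).
#' @param kappa curvature used to validate that the emission energy
#'   \code{dg_ctgs0 - kappa*x_ct^2/2} is positive.
#'
#' @return An object of class \code{ligand_photophysics}.
#' @examples
#' # fitted parameters of a p38alpha-kinase inhibitor complex
#' lig <- ligand_photophysics(x_ct = 0.891, dg_ctgs0 = 3.347, dg_ctgsn = 3.223)
#' reorg_energy(lig)
#' @export
ligand_photophysics <- function(x_ct, dg_ctgs0, dg_ctgsn, kappa = 1) {
  stopifnot(is.numeric(x_ct), length(x_ct) == 1, x_ct > 0,
            is.numeric(dg_ctgs0), length(dg_ctgs0) == 1,
            is.numeric(dg_ctgsn), length(dg_ctgsn) == 1)
  reorg <- kappa * x_ct^2 / 2
  if (dg_ctgs0 <= reorg)
    stop("dg_ctgs0 (", dg_ctgs0, " eV) must exceed the reorganization energy (",
         signif(reorg, 4), " eV) for a positive emission energy")
  structure(list(x_ct = x_ct, dg_ctgs0 = dg_ctgs0, dg_ctgsn = dg_ctgsn),
            class = "ligand_photophysics")
}

#' @export
print.ligand_photophysics <- function(x, ...) {
  cat("Ligand photophysics (CT fluorophore)\n")
  cat(sprintf("  x_CT: %.3f eV^0.5   reorg (kappa=1): %.3f eV\n",
              x$x_ct, reorg_energy(x)))
  cat(sprintf("  dG_CTGS0: %.3f eV   dG_CTGSN: %.3f eV\n",
              x$dg_ctgs0, x$dg_ctgsn))
  invisible(x)
}

#' Ligand reorganization energy
#'
#' Marcus reorganization energy of the CT-to-GS transition,
#' \eqn{\kappa x_{CT}^2 / 2}, equal to half the Stokes shift.
#'
#' @param lig a \code{\link{ligand_photophysics}} object.
#' @param kappa curvature constant (1 by default, matching the
#'   dimensionless-coordinate convention).
#' @return Reorganization energy in eV.
#' @export
reorg_energy <- function(lig, kappa = 1) {
  kappa * lig$x_ct^2 / 2
}

#' Parametric free-energy landscape specification
#'
#' The ground-state free-energy landscape assigns minimum free energy
#' \eqn{A i^b} to microstate \eqn{i}, for \code{m} microstates indexed
#' \code{i = 0 ... m - 1}, equally spaced along the collective coordinate by
#' \code{x_gs}.  \code{b = 1} is a linear ramp, \code{b = 2} quadratic
#' (harmonic), \code{b = 3} cubic.  The landscape span (top minus bottom
#' minimum) is \eqn{A (m-1)^b}.
#'
#' @param a energy scale A in eV (non-negative).
#' @param b landscape exponent (positive).
#' @param x_gs microstate spacing along x (eV^0.5, non-negative).
#' @param m number of microstates (>= 1).
#'
#' @return An object of class \code{fel_spec}.
#' @examples
#' # fitted quadratic landscape of the p38alpha complex
#' fel <- fel_spec(a = 0.00178, b = 2, x_gs = 0.153, m = 10)
#' fel_span(fel)  # 0.144 eV
#' @export
fel_spec <- function(a, b, x_gs, m) {
  stopifnot(is.numeric(a), length(a) == 1, a >= 0,
            is.numeric(b), length(b) == 1, b > 0,
            is.numeric(x_gs), length(x_gs) == 1, x_gs >= 0,
            is.numeric(m), length(m) == 1, m >= 1, m == round(m))
  structure(list(a = a, b = b, x_gs = x_gs, m = as.integer(m)),
            class = "fel_spec")
}

#' @export
print.fel_spec <- function(x, ...) {
  cat(sprintf("Free-energy landscape A*i^b: A = %g eV, b = %g, x_GS = %g, m = %d states\n",
              x$a, x$b, x$x_gs, x$m))
  cat(sprintf("  span A*(m-1)^b = %.4f eV\n", fel_span(x)))
  invisible(x)
}

#' Landscape span
#'
#' Free-energy difference between the least and most stable microstate
#' minima, \eqn{A (m-1)^b}.
#'
#' @param fel a \code{\link{fel_spec}}.
#' @return Span in eV.
#' @export
fel_span <- function(fel) {
  if (fel$m == 1) return(0)
  fel$a * (fel$m - 1)^fel$b
}

.check_index <- function(i, m) {
  if (any(i < 0 | i > m - 1 | i != round(i)))
    stop("microstate index i = ", paste(i, collapse = ", "),
         " out of range for m = ", m, " states (valid: 0..", m - 1, ")")
  invisible(as.integer(i))
}

#' CT-GS free-energy gap of a microstate
#'
#' Linear interpolation of the CT-GS gap between the most stable state
#' (\code{dg_ctgs0} at i = 0) and the least stable state (\code{dg_ctgsn} at
#' i = m - 1).  With a single microstate the gap is \code{dg_ctgs0}.
#'
#' @param i microstate index (0-based; vectorized).
#' @param lig a \code{\link{ligand_photophysics}}.
#' @param m number of microstates.
#' @return Gap(s) in eV.
#' @export
ct_gap <- function(i, lig, m) {
  .check_index(i, m)
  if (m == 1) return(rep(lig$dg_ctgs0, length(i)))
  lig$dg_ctgs0 + (i / (m - 1)) * (lig$dg_ctgsn - lig$dg_ctgs0)
}

#' Ground-state free-energy surface of a microstate
#'
#' \eqn{G_{GS,i}(x) = \kappa (x - i x_{GS})^2 / 2 + A i^b}: a harmonic well
#' displaced by \code{i * x_gs} along x and offset by the landscape value.
#'
#' @param i microstate index (0-based).
#' @param x collective coordinate (vectorized).
#' @param fel a \code{\link{fel_spec}}.
#' @param cfg a \code{\link{model_config}}.
#' @return Free energy in eV at each \code{x}.
#' @export
gs_free_energy <- function(i, x, fel, cfg = model_config()) {
  .check_index(i, fel$m)
  cfg$kappa * (x - i * fel$x_gs)^2 / 2 + fel$a * i^fel$b
}

#' CT-state free-energy surface of a microstate
#'
#' \eqn{G_{CT,i}(x) = \kappa (x - i x_{GS} - x_{CT})^2 / 2 + A i^b +
#' gap(i)}: the GS well of microstate \code{i} displaced by the CT
#' displacement \code{x_ct} and raised by the interpolated CT-GS gap.
#'
#' @inheritParams gs_free_energy
#' @param lig a \code{\link{ligand_photophysics}}.
#' @return Free energy in eV at each \code{x}.
#' @export
ct_free_energy <- function(i, x, fel, lig, cfg = model_config()) {
  .check_index(i, fel$m)
  cfg$kappa * (x - i * fel$x_gs - lig$x_ct)^2 / 2 +
    fel$a * i^fel$b + ct_gap(i, lig, fel$m)
}

#' Boltzmann weights of the microstates at a coordinate value
#'
#' Normalized ground-state populations
#' \eqn{W_i(x) = \exp(-G_{GS,i}(x)/k_bT) / Z(x)} with
#' \eqn{Z(x) = \sum_i \exp(-G_{GS,i}(x)/k_bT)}.  Exponentials are stabilized
#' by subtracting the minimum free energy before exponentiation (the shift
#' cancels in the normalization, as does any constant prefactor of the
#' Boltzmann density).
#'
#' @param x a single coordinate value.
#' @param fel a \code{\link{fel_spec}}.
#' @param cfg a \code{\link{model_config}}.
#' @return A list with \code{x}, \code{weights} (length \code{m}, summing to
#'   1) and \code{z}, the stabilized partition value.
#' @export
boltzmann_weights <- function(x, fel, cfg = model_config()) {
  stopifnot(is.numeric(x), length(x) == 1, is.finite(x))
  i <- seq_len(fel$m) - 1L
  g <- cfg$kappa * (x - i * fel$x_gs)^2 / 2 + fel$a * i^fel$b
  kt <- cfg$k_b * cfg$temperature_K
  e <- exp(-(g - min(g)) / kt)
  z <- sum(e)
  structure(list(x = x, weights = e / z, z = z), class = "microstate_weights")
}

## Weight matrix over a coordinate grid: rows = microstates, cols = x values.
## Column-wise max-shift stabilization.
.weight_matrix <- function(x, fel, cfg) {
  i <- seq_len(fel$m) - 1L
  kt <- cfg$k_b * cfg$temperature_K
  g <- outer(i * fel$x_gs, x, function(d, xx) cfg$kappa * (xx - d)^2 / 2) +
    fel$a * i^fel$b
  g <- sweep(g, 2, apply(g, 2, min))
  e <- exp(-g / kt)
  sweep(e, 2, colSums(e), "/")
}

## Lean ensemble sweep used by the fitting hot path: one weight matrix for
## both energies, no data.frame or class overhead.  Returns NULL if the
## excitation energy is not strictly decreasing in x.
.ensemble_curve <- function(lig, fel, cfg, mode = "printed") {
  x <- seq(cfg$x_min, cfg$x_max, length.out = cfg$n_grid)
  i <- seq_len(fel$m) - 1L
  kt <- cfg$k_b * cfg$temperature_K
  g <- outer(i * fel$x_gs, x, function(d, xx) cfg$kappa * (xx - d)^2 / 2) +
    fel$a * i^fel$b
  ## global-min shift: all exponents <= 0, no overflow; partial underflow
  ## is harmless because every column retains its dominant state
  e <- exp(-(g - min(g)) / kt)
  s <- colSums(e)
  reorg <- cfg$kappa * lig$x_ct^2 / 2
  gap <- ct_gap(i, lig, fel$m)
  wgap <- drop(crossprod(e, gap)) / s
  ex <- if (mode == "printed") {
    wgap + reorg - cfg$kappa * x * lig$x_ct
  } else {
    wgap + reorg - cfg$kappa * lig$x_ct *
      (x - drop(crossprod(e, i * fel$x_gs)) / s)
  }
  if (any(diff(ex) >= 0)) return(NULL)
  em <- wgap - reorg
  list(x = x, ex_ev = ex, em_ev = em,
       ex_nm = .hc_ev_nm / ex, em_nm = .hc_ev_nm / em)
}

#' Per-microstate absorption energy
#'
#' Vertical GS-to-CT absorption energy of microstate \code{i} at coordinate
#' \code{x}.  The default (\code{mode = "printed"}) is
#' \eqn{gap(i) + \kappa x_{CT}^2/2 - \kappa x x_{CT}}, identical in x-slope
#' for every microstate.  \code{mode = "strict"} instead takes the vertical
#' gap between the two surfaces directly,
#' \eqn{G_{CT,i}(x) - G_{GS,i}(x)}, which adds a
#' \eqn{\kappa i x_{GS} x_{CT}} cross-term; it is provided as a diagnostic
#' (see the methods vignette).
#'
#' @inheritParams ct_free_energy
#' @param mode \code{"printed"} (default) or \code{"strict"}.
#' @return Absorption energy in eV at each \code{x}.
#' @export
microstate_abs_energy <- function(i, x, fel, lig, cfg = model_config(),
                                  mode = c("printed", "strict")) {
  mode <- match.arg(mode)
  .check_index(i, fel$m)
  reorg <- cfg$kappa * lig$x_ct^2 / 2
  gap <- ct_gap(i, lig, fel$m)
  if (mode == "printed") {
    gap + reorg - cfg$kappa * x * lig$x_ct
  } else {
    gap + reorg - cfg$kappa * (x - i * fel$x_gs) * lig$x_ct
  }
}

#' Per-microstate emission energy
#'
#' Peak emission energy from the relaxed CT minimum of microstate \code{i}:
#' \eqn{gap(i) - \kappa x_{CT}^2/2}.  Emission is independent of the
#' excitation coordinate within a microstate (vibrational relaxation in the
#' local CT well precedes emission), so a single microstate shows zero REES.
#'
#' @param i microstate index (0-based, vectorized).
#' @param fel a \code{\link{fel_spec}}.
#' @param lig a \code{\link{ligand_photophysics}}.
#' @param cfg a \code{\link{model_config}}.
#' @return Emission energy in eV.
#' @export
microstate_em_energy <- function(i, fel, lig, cfg = model_config()) {
  .check_index(i, fel$m)
  ct_gap(i, lig, fel$m) - cfg$kappa * lig$x_ct^2 / 2
}

#' Ensemble absorption energy
#'
#' Boltzmann-weighted mean of the per-microstate absorption energies at
#' coordinate \code{x}.
#'
#' @param x coordinate value(s).
#' @inheritParams microstate_abs_energy
#' @return Ensemble absorption energy in eV at each \code{x}.
#' @export
ensemble_abs_energy <- function(x, fel, lig, cfg = model_config(),
                                mode = c("printed", "strict")) {
  mode <- match.arg(mode)
  w <- .weight_matrix(x, fel, cfg)
  i <- seq_len(fel$m) - 1L
  reorg <- cfg$kappa * lig$x_ct^2 / 2
  gap <- ct_gap(i, lig, fel$m)
  if (mode == "printed") {
    drop(crossprod(w, gap)) + reorg - cfg$kappa * x * lig$x_ct
  } else {
    base <- outer(gap + reorg, x, function(g, xx) g) -
      cfg$kappa * lig$x_ct * outer(-i * fel$x_gs, x, "+")
    colSums(w * base)
  }
}

#' Ensemble mean emission energy
#'
#' Boltzmann-weighted mean of the per-microstate (x-independent) emission
#' energies; the x dependence enters only through the weights.  For a single
#' microstate the result is constant in x (zero REES).
#'
#' @param x coordinate value(s).
#' @param fel a \code{\link{fel_spec}}.
#' @param lig a \code{\link{ligand_photophysics}}.
#' @param cfg a \code{\link{model_config}}.
#' @return Ensemble emission energy in eV at each \code{x}.
#' @export
ensemble_em_energy <- function(x, fel, lig, cfg = model_config()) {
  w <- .weight_matrix(x, fel, cfg)
  em <- microstate_em_energy(seq_len(fel$m) - 1L, fel, lig, cfg)
  drop(crossprod(w, em))
}
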