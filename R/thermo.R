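## Energy-unit conversion constants (per eV)
.ev_to <- c(ev = 1, kj_mol = 96.485, kcal_mol = 23.0605)

#' Free-energy gap between successive microstate minima
#'
#' \eqn{\Delta G_{GS(i+1,i)} = A (i+1)^b - A i^b}.  For a linear ramp
#' (\code{b = 1}) every gap equals A; for the quadratic landscape it is
#' \eqn{A (2i + 1)}, increasing with i.
#'
#' @param i lower state index (0-based; valid 0..m-2; vectorized).
#' @param fel a \code{\link{fel_spec}}.
#' @return Gap(s) in eV.
#' @export
state_gap <- function(i, fel) {
  if (any(i < 0 | i > fel$m - 2 | i != round(i)))
    stop("gap index i = ", paste(i, collapse = ", "),
         " out of range (valid: 0..", fel$m - 2, ")")
  fel$a * ((i + 1)^fel$b - i^fel$b)
}

#' Ground-state reorganization energy
#'
#' \eqn{RE = \kappa x_{GS}^2 / 2}: the Marcus reorganization energy
#' associated with moving the ligand between adjacent microstate wells,
#' which sets the inter-microstate activation barriers.
#'
#' @param fel a \code{\link{fel_spec}}.
#' @param cfg a \code{\link{model_config}}.
#' @return Energy in eV.
#' @export
gs_reorg <- function(fel, cfg = model_config()) {
  cfg$kappa * fel$x_gs^2 / 2
}

#' Marcus activation barrier between successive microstates
#'
#' \eqn{\Delta G^{act}_{i+1,i} = (\Delta G_{GS(i+1,i)} + RE)^2 / (4 RE)}
#' from the crossing of the two displaced harmonic wells.
#'
#' @inheritParams state_gap
#' @param cfg a \code{\link{model_config}}.
#' @return Barrier(s) in eV.
#' @export
activation_barrier <- function(i, fel, cfg = model_config()) {
  re <- gs_reorg(fel, cfg)
  if (re <= 0)
    stop("activation barrier undefined for zero ground-state ",
         "reorganization energy (x_gs = 0)")
  (state_gap(i, fel) + re)^2 / (4 * re)
}

#' Convert between energy units
#'
#' Supported units: \code{"eV"}, \code{"kJ/mol"}, \code{"kcal/mol"} and
#' \code{"kbT"} (thermal energy at \code{temperature_K}).  Conversions pass
#' through eV using 1 eV = 96.485 kJ/mol = 23.0605 kcal/mol.
#'
#' @param value numeric value(s) in \code{from} units.
#' @param from,to unit names.
#' @param temperature_K temperature used for the kbT unit.
#' @return Value(s) in \code{to} units.
#' @examples
#' convert_energy(0.144, "eV", "kbT")      # ~5.6
#' convert_energy(0.144, "eV", "kcal/mol") # ~3.3
#' @export
convert_energy <- function(value, from, to, temperature_K = 298) {
  norm <- function(u) {
    key <- c("ev" = "ev", "kj/mol" = "kj_mol", "kcal/mol" = "kcal_mol",
             "kbt" = "kbt")[tolower(u)]
    if (is.na(key)) stop("unknown energy unit: '", u,
                         "' (use eV, kJ/mol, kcal/mol or kbT)")
    key
  }
  from <- norm(from); to <- norm(to)
  kbt_ev <- .kb_ev * temperature_K
  ev <- if (from == "kbt") value * kbt_ev else value / .ev_to[[from]]
  if (to == "kbt") ev / kbt_ev else ev * .ev_to[[to]]
}

#' Binding free energy from a dissociation constant
#'
#' \eqn{\Delta G = k_bT \ln(K_d / 1\,M)} against the 1 M standard state;
#' negative for sub-molar dissociation constants.
#'
#' @param kd dissociation (or inhibition) constant in molar units.
#' @param temperature_K temperature in kelvin.
#' @return A list with \code{kbt} (dimensionless multiples of
#'   \eqn{k_bT}), \code{ev} and \code{kcal_mol}.
#' @examples
#' kd_to_binding_energy(0.560e-6)$kbt  # ~ -14.4
#' @export
kd_to_binding_energy <- function(kd, temperature_K = 298) {
  if (!is.numeric(kd) || any(kd <= 0))
    stop("dissociation constant must be positive (molar units)")
  kbt <- log(kd)
  ev <- kbt * .kb_ev * temperature_K
  list(kbt = kbt, ev = ev, kcal_mol = ev * .ev_to[["kcal_mol"]])
}

#' Decompose total binding free energy into association and intrusion
#'
#' The total protein-ligand binding free energy is modelled as the sum of a
#' surface-association (encounter-complex) term and an intrusion term - the
#' free energy of moving from the least stable (surface-proximal) bound
#' microstate to the most stable interior state, which the fitted landscape
#' span provides.  The association term is recovered by difference.
#'
#' @param dg_total_kcal total binding free energy (kcal/mol, negative
#'   favourable), e.g. from \code{\link{kd_to_binding_energy}}.
#' @param dg_intrusion_kcal intrusion free energy (kcal/mol), e.g. the
#'   negated landscape span converted to kcal/mol.
#' @return An object of class \code{binding_decomposition} with
#'   \code{dg_total_kcal}, \code{dg_intrusion_kcal}, \code{dg_assoc_kcal}.
#' @examples
#' binding_decomposition(-8.3, -3.3)  # association -5.0 kcal/mol
#' @export
binding_decomposition <- function(dg_total_kcal, dg_intrusion_kcal) {
  stopifnot(is.finite(dg_total_kcal), is.finite(dg_intrusion_kcal))
  structure(list(dg_total_kcal = dg_total_kcal,
                 dg_intrusion_kcal = dg_intrusion_kcal,
                 dg_assoc_kcal = dg_total_kcal - dg_intrusion_kcal),
            class = "binding_decomposition")
}

#' @export
print.binding_decomposition <- function(x, ...) {
  cat("Binding free-energy decomposition (kcal/mol)\n")
  cat(sprintf("  total: %.2f = association %.2f + intrusion %.2f\n",
              x$dg_total_kcal, x$dg_assoc_kcal, x$dg_intrusion_kcal))
  invisible(x)
}

#' Full landscape report
#'
#' Assembles the per-microstate minima \eqn{A i^b}, successive gaps, the
#' ground-state reorganization energy, the Marcus activation barriers, and
#' the landscape span for a fitted free-energy landscape.
#'
#' @param fel a \code{\link{fel_spec}} with at least 2 microstates.
#' @param cfg a \code{\link{model_config}}.
#' @return An object of class \code{landscape_report} with fields
#'   \code{minima_ev} (length m), \code{gaps_ev} and \code{barriers_ev}
#'   (length m-1), \code{gs_reorg_ev} and \code{span_ev}.
#' @export
landscape_report <- function(fel, cfg = model_config()) {
  stopifnot(fel$m >= 2)
  i <- seq_len(fel$m) - 1L
  gaps <- state_gap(i[-fel$m], fel)
  structure(list(minima_ev = fel$a * i^fel$b,
                 gaps_ev = gaps,
                 gs_reorg_ev = gs_reorg(fel, cfg),
                 barriers_ev = activation_barrier(i[-fel$m], fel, cfg),
                 span_ev = fel_span(fel),
                 fel = fel),
            class = "landscape_report")
}

#' @export
print.landscape_report <- function(x, ...) {
  cat(sprintf("Free-energy landscape report (%d microstates)\n", x$fel$m))
  cat(sprintf("  span: %.4f eV   ground-state reorg: %.4f eV\n",
              x$span_ev, x$gs_reorg_ev))
  cat(sprintf("  largest gap: %.4f eV   largest barrier: %.4f eV\n",
              max(x$gaps_ev), max(x$barriers_ev)))
  invisible(x)
}

#' Export a landscape report as CSV
#'
#' One row per microstate with its minimum, and (for all but the top state)
#' the gap and activation barrier to the next state.
#'
#' @param report a \code{\link{landscape_report}}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_landscape_csv <- function(report, path) {
  m <- length(report$minima_ev)
  df <- data.frame(state = seq_len(m) - 1L,
                   minimum_ev = report$minima_ev,
                   gap_ev = c(report$gaps_ev, NA),
                   barrier_ev = c(report$barriers_ev, NA))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
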