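# Shared parameter sets: the two fitted kinase-inhibitor complexes and the
# simulation ligand used for the curve-shape families.

p38a_ligand <- function() ligand_photophysics(0.891, 3.347, 3.223)
aph_ligand <- function() ligand_photophysics(1.076, 3.172, 3.015)
sim_ligand <- function() ligand_photophysics(0.89, 3.346, 3.223)

p38a_fel <- function() fel_spec(0.00178, 2, 0.153, 10)
aph_fel <- function() fel_spec(0.00172, 2, 0.258, 5)

# independent brute-force ensemble oracle: plain loops, no shared code with
# the vectorized implementation
oracle_ensemble <- function(x, fel, lig, cfg = model_config()) {
  kt <- cfg$k_b * cfg$temperature_K
  reorg <- cfg$kappa * lig$x_ct^2 / 2
  abs_e <- em_e <- numeric(length(x))
  for (j in seq_along(x)) {
    p <- numeric(fel$m)
    a_j <- e_j <- 0
    for (i in 0:(fel$m - 1)) {
      g <- cfg$kappa * (x[j] - i * fel$x_gs)^2 / 2 + fel$a * i^fel$b
      p[i + 1] <- exp(-g / kt)
    }
    p <- p / sum(p)
    for (i in 0:(fel$m - 1)) {
      gap <- if (fel$m == 1) lig$dg_ctgs0 else
        lig$dg_ctgs0 + (i / (fel$m - 1)) * (lig$dg_ctgsn - lig$dg_ctgs0)
      a_j <- a_j + p[i + 1] * (gap + reorg - cfg$kappa * x[j] * lig$x_ct)
      e_j <- e_j + p[i + 1] * (gap - reorg)
    }
    abs_e[j] <- a_j
    em_e[j] <- e_j
  }
  list(abs_ev = abs_e, em_ev = em_e)
}
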