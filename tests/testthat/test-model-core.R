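test_that("ground-state surfaces follow the displaced-harmonic form", {
  fel <- fel_spec(0.0025, 1, 0.1, 10)
  expect_equal(gs_free_energy(0, 0, fel), 0)
  # offset plus well displacement, evaluated by hand
  expect_equal(gs_free_energy(1, 0, fel), 0.5 * 0.01 + 0.0025)
  # top-microstate minimum equals the fitted landscape span
  expect_equal(gs_free_energy(9, 9 * 0.153, p38a_fel()), 0.14418,
               tolerance = 1e-12)
  expect_error(gs_free_energy(10, 0, fel), "out of range")
  expect_error(gs_free_energy(-1, 0, fel), "out of range")
})

test_that("CT surfaces carry the interpolated gap and displacement", {
  lig <- p38a_ligand()
  fel <- p38a_fel()
  # CT minimum of a single-microstate system sits at dg_ctgs0
  fel1 <- fel_spec(0, 1, 0, 1)
  expect_equal(ct_free_energy(0, lig$x_ct, fel1, lig), lig$dg_ctgs0)
  # hand evaluation at x = 0 for the bottom state
  expect_equal(ct_free_energy(0, 0, fel, lig), 0.5 * 0.891^2 + 3.347)
  # top state at its own CT minimum: landscape value plus dg_ctgsn
  m <- fel$m
  x_top <- (m - 1) * fel$x_gs + lig$x_ct
  expect_equal(ct_free_energy(m - 1, x_top, fel, lig),
               fel$a * (m - 1)^fel$b + lig$dg_ctgsn)
})

test_that("gap interpolation hits both anchors and is linear between", {
  lig <- p38a_ligand()
  expect_equal(ct_gap(0, lig, 10), lig$dg_ctgs0)
  expect_equal(ct_gap(9, lig, 10), lig$dg_ctgsn)
  mid <- ct_gap(4, lig, 9)  # middle of 9 states
  expect_equal(mid, (lig$dg_ctgs0 + lig$dg_ctgsn) / 2)
  expect_equal(ct_gap(0, lig, 1), lig$dg_ctgs0)
})

test_that("Boltzmann weights are normalized and match direct evaluation", {
  # single state: trivially 1
  expect_equal(boltzmann_weights(0.7, fel_spec(0, 1, 0, 1))$weights, 1)
  # symmetric two-state point
  w <- boltzmann_weights(0.05, fel_spec(0, 1, 0.1, 2))
  expect_equal(w$weights, c(0.5, 0.5))
  # direct-ratio oracle
  w <- boltzmann_weights(0, fel_spec(0.01, 1, 0.1, 2))
  kt <- 8.617333262e-5 * 298
  r <- exp(-(0.5 * 0.01 + 0.01) / kt)  # G1 = 0.015 eV, G0 = 0
  expect_equal(w$weights[2] / w$weights[1], r, tolerance = 1e-12)
  # normalization across a grid for random parameter draws
  withr::with_seed(42, {
    for (rep in 1:10) {
      fel <- fel_spec(runif(1, 0, 0.05), runif(1, 0.5, 3),
                      runif(1, 0, 0.3), sample(1:8, 1))
      sums <- vapply(seq(-1, 2, length.out = 31),
                     function(x) sum(boltzmann_weights(x, fel)$weights),
                     numeric(1))
      expect_true(all(abs(sums - 1) < 1e-12))
    }
  })
})

test_that("per-microstate energies satisfy the Stokes and gap identities", {
  lig <- p38a_ligand()
  fel <- p38a_fel()
  i <- 0:9
  ab0 <- microstate_abs_energy(i, 0, fel, lig)
  em <- microstate_em_energy(i, fel, lig)
  # absorption minus emission at the band origin is twice the reorg energy
  expect_equal(ab0 - em, rep(2 * reorg_energy(lig), 10), tolerance = 1e-12)
  # the mean of absorption and emission recovers the CT-GS gap exactly
  expect_equal((ab0 + em) / 2, ct_gap(i, lig, 10), tolerance = 1e-15)
  # anchored endpoint values
  expect_equal(ab0[1], 3.347 + 0.891^2 / 2)
  expect_equal(ab0[10], 3.223 + 0.891^2 / 2)
  expect_equal(energy_to_wavelength(em[1]), 420.3, tolerance = 1e-3)
  expect_equal(energy_to_wavelength(em[10]), 438.7, tolerance = 1e-3)
})

test_that("strict-surface absorption differs from the printed form by the
           spacing cross-term", {
  lig <- p38a_ligand()
  fel <- p38a_fel()
  for (i in c(0, 3, 9)) {
    d <- microstate_abs_energy(i, 0.4, fel, lig, mode = "strict") -
      microstate_abs_energy(i, 0.4, fel, lig, mode = "printed")
    expect_equal(d, i * fel$x_gs * lig$x_ct, tolerance = 1e-12)
  }
})

test_that("ensemble energies equal the brute-force oracle", {
  withr::with_seed(7, {
    for (rep in 1:8) {
      fel <- fel_spec(runif(1, 0, 0.03), runif(1, 0.8, 2.5),
                      runif(1, 0.02, 0.3), sample(1:5, 1))
      lig <- ligand_photophysics(runif(1, 0.5, 1.2), runif(1, 3, 3.6),
                                 runif(1, 2.8, 3.2))
      x <- runif(5, -1, 2)
      o <- oracle_ensemble(x, fel, lig)
      expect_equal(ensemble_abs_energy(x, fel, lig), o$abs_ev,
                   tolerance = 1e-12)
      expect_equal(ensemble_em_energy(x, fel, lig), o$em_ev,
                   tolerance = 1e-12)
    }
  })
})

test_that("a single microstate shows zero red-edge shift", {
  lig <- p38a_ligand()
  fel <- fel_spec(0, 1, 0, 1)
  em <- ensemble_em_energy(seq(-1, 2, length.out = 201), fel, lig)
  expect_lt(max(em) - min(em), 1e-12)
})

test_that("emission shifts red for stabilized CT states and blue otherwise", {
  fel <- fel_spec(0.0025, 2, 0.15, 10)
  x <- seq(-1, 2, length.out = 501)
  # case (i): top-state CT gap below bottom-state gap -> red shift
  em_i <- ensemble_em_energy(x, fel, ligand_photophysics(0.89, 3.346, 3.223))
  expect_true(all(diff(em_i) <= 1e-12))
  # case (ii): reversed gaps -> blue shift
  em_ii <- ensemble_em_energy(x, fel, ligand_photophysics(0.89, 3.223, 3.346))
  expect_true(all(diff(em_ii) >= -1e-12))
})

test_that("constructors reject invalid parameters", {
  expect_error(model_config(n_grid = 2))
  expect_error(model_config(x_min = 2, x_max = -1))
  expect_error(fel_spec(-0.1, 2, 0.1, 5))
  expect_error(fel_spec(0.1, 2, 0.1, 0))
  expect_error(ligand_photophysics(-1, 3.3, 3.2))
  # emission energy must stay positive
  expect_error(ligand_photophysics(3, 3.3, 3.2), "reorganization")
})
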