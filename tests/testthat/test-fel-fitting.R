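test_that("sigmoid fitting recovers known parameters", {
  truth <- c(em_blue = 421, em_red = 439, mid = 390, width = 12)
  ex <- seq(340, 440, length.out = 15)
  em <- truth["em_red"] + (truth["em_blue"] - truth["em_red"]) /
    (1 + exp((ex - truth["mid"]) / truth["width"]))
  sig <- fit_sigmoid(rees_dataset(ex, em))
  expect_equal(sig$em_blue_nm, 421, tolerance = 1e-6)
  expect_equal(sig$em_red_nm, 439, tolerance = 1e-6)
  expect_equal(sig$mid_nm, 390, tolerance = 1e-6)
  expect_equal(sig$width_nm, 12, tolerance = 1e-6)
  expect_lt(sig$residual_ss, 1e-10)
  # with Gaussian noise the asymptotes stay within a nanometre
  em_noisy <- em + withr::with_seed(101, rnorm(length(ex), 0, 0.3))
  sig_n <- fit_sigmoid(rees_dataset(ex, em_noisy))
  expect_lt(abs(sig_n$em_blue_nm - 421), 1)
  expect_lt(abs(sig_n$em_red_nm - 439), 1)
})

test_that("sigmoid fitting guards its preconditions", {
  expect_error(fit_sigmoid(rees_dataset(1:4 * 10 + 300, c(420, 425, 435, 438))),
               "at least 5")
  flat <- fit_sigmoid(rees_dataset(seq(350, 420, 10), rep(430, 8)))
  expect_true(flat$degenerate)
  expect_equal(flat$em_blue_nm, flat$em_red_nm)
})

test_that("the landscape objective is zero at truth and grows away from it", {
  fx <- make_reference_fixtures()
  ds <- fx$p38a$dataset
  lig <- fx$p38a$ligand
  fel <- fx$p38a$fel
  # data were generated from this very model
  expect_lt(fel_objective(fel, lig, ds), 1e-10)
  # +50% on the energy scale strictly increases the misfit
  fel_off <- fel_spec(fel$a * 1.5, fel$b, fel$x_gs, fel$m)
  expect_gt(fel_objective(fel_off, lig, ds), fel_objective(fel, lig, ds))
  # fitted quadratic beats fitted linear and cubic parameter sets against
  # the reference sigmoid
  sig <- fit_sigmoid(ds)
  s_quad <- fel_objective(fel, lig, sig, ds$ex_nm)
  s_lin <- fel_objective(fel_spec(0.0083, 1, 0.078, 10), lig, sig, ds$ex_nm)
  s_cub <- fel_objective(fel_spec(0.00049, 3, 0.305, 10), lig, sig, ds$ex_nm)
  expect_lt(s_quad, s_lin)
  expect_lt(s_quad, s_cub)
  # disjoint wavelength ranges are an error
  expect_error(fel_objective(fel, lig, sig, c(10, 20)), "overlap")
})

test_that("AIC follows 2k + n ln(LSQ)", {
  expect_equal(aic(3, 10, 1), 6)
  expect_equal(aic(0, 10, 10), 10 * log(10))
  expect_equal(10 * log(10), 23.0, tolerance = 0.05)
  expect_equal(10 * log(4), 13.86, tolerance = 0.01)
  # more parameters win when the fit improves enough
  expect_lt(aic(4, 10, 4), aic(2, 10, 10))
  expect_error(aic(2, 10, 0), "positive")
})

test_that("landscape fits recover generating parameters", {
  fx <- make_reference_fixtures()
  fit <- fit_fel(fx$p38a$dataset, fx$p38a$ligand, m = 10, b = 2)
  expect_lt(abs(fit$fel$a - 0.00178) / 0.00178, 0.05)
  expect_lt(abs(fit$fel$x_gs - 0.153) / 0.153, 0.05)
  expect_false(fit$at_bound)
  # flat data drive the fit to a degenerate corner of parameter space
  flat_ds <- rees_dataset(seq(350, 420, length.out = 8),
                          rep(430, 8) + seq(0, 1e-3, length.out = 8))
  sig_flat <- fit_sigmoid(flat_ds)
  fit_flat <- fit_fel(sig_flat, fx$p38a$ligand, m = 10, b = 2)
  expect_true(fit_flat$at_bound)
})

test_that("model scans rank candidates and honour ties and failures", {
  fx <- make_reference_fixtures()
  ds <- fx$aph$dataset
  cmp <- scan_models(ds, fx$aph$ligand, m_range = 4:6, b_values = 2)
  expect_equal(cmp$table$m[cmp$best], 5)
  expect_equal(best_model(cmp)$slsq, min(cmp$table$slsq))
  # single-candidate scan returns that candidate
  cmp1 <- scan_models(ds, fx$aph$ligand, m_range = 5, b_values = 2)
  expect_equal(cmp1$best, 1L)
  expect_equal(cmp1$results[[1]]$n_free_params, 2L)
  # scanning m adds a free parameter to the AIC bookkeeping
  expect_equal(best_model(cmp)$n_free_params, 3L)
})

test_that("refitting a curve simulated from a fitted landscape is
           self-consistent", {
  fx <- make_reference_fixtures()
  fit <- fit_fel(fx$aph$dataset, fx$aph$ligand, m = 5, b = 2)
  ds2 <- generate_rees_dataset(fx$aph$ligand, fit$fel)
  fit2 <- fit_fel(ds2, fx$aph$ligand, m = 5, b = 2)
  expect_lt(abs(fit2$fel$a - fit$fel$a) / fit$fel$a, 0.01)
  expect_lt(abs(fit2$fel$x_gs - fit$fel$x_gs) / fit$fel$x_gs, 0.01)
})

test_that("the full pipeline returns a coherent, self-consistent analysis", {
  fx <- make_reference_fixtures()
  res <- analyze_rees(fx$p38a$dataset, abs_max = fx$p38a$abs_max_ev,
                      m_range = 9:11, b_values = 2, target = "data",
                      kd = 0.560e-6)
  # the chosen model minimizes the criterion over the scanned candidates
  expect_equal(res$best$slsq, min(res$comparison$table$slsq))
  expect_true(res$best$fel$m %in% 9:11)
  # ligand calibration reproduces the sigmoid endpoints exactly
  expect_equal(res$ligand$dg_ctgs0 - res$ligand$dg_ctgsn,
               wavelength_to_energy(res$sigmoid$em_blue_nm) -
                 wavelength_to_energy(res$sigmoid$em_red_nm),
               tolerance = 1e-12)
  expect_equal(res$ligand$dg_ctgs0 - reorg_energy(res$ligand),
               wavelength_to_energy(res$sigmoid$em_blue_nm),
               tolerance = 1e-12)
  # landscape block matches the winning model, binding split is additive
  expect_equal(res$landscape$span_ev, fel_span(res$best$fel))
  expect_equal(res$binding$dg_assoc_kcal,
               res$binding$dg_total_kcal - res$binding$dg_intrusion_kcal)
  expect_equal(res$binding$dg_intrusion_kcal,
               -convert_energy(res$landscape$span_ev, "eV", "kcal/mol"))
})
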