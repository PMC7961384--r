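test_that("energy/wavelength conversions are exact inverses", {
  expect_equal(energy_to_wavelength(2.950), 420.3, tolerance = 1e-3)
  expect_equal(energy_to_wavelength(2.826), 438.7, tolerance = 1e-3)
  e <- c(0.5, 1.7, 2.95, 4.1)
  expect_equal(wavelength_to_energy(energy_to_wavelength(e)), e,
               tolerance = 1e-12)
  expect_error(energy_to_wavelength(0), "positive")
  expect_error(wavelength_to_energy(-300), "positive")
})

test_that("simulated curves reproduce the ligand emission limits", {
  crv <- simulate_rees_curve(sim_ligand(), fel_spec(0.0025, 1, 0.1, 10))
  s <- summarize_curve(crv)
  # asymptotic emission window of the p38a-like simulation family
  expect_equal(s$em_blue_nm, energy_to_wavelength(3.346 - 0.89^2 / 2),
               tolerance = 0.2)
  expect_equal(s$em_red_nm, energy_to_wavelength(3.223 - 0.89^2 / 2),
               tolerance = 0.2)
  # emission is monotone in excitation for this landscape class
  o <- order(crv$ex_nm)
  expect_true(all(diff(crv$em_nm[o]) >= -1e-9))
})

test_that("single-microstate curves are flat and flagged", {
  crv <- simulate_rees_curve(p38a_ligand(), fel_spec(0, 1, 0, 1))
  expect_lt(max(crv$em_nm) - min(crv$em_nm), 1e-6)
  s <- summarize_curve(crv)
  expect_false(s$midpoint_defined)
  expect_true(is.na(s$midpoint_ex_nm))
})

test_that("midpoint summary is exact on an analytic sigmoid", {
  ex <- seq(300, 500, length.out = 2001)
  em <- 430 - 20 / (1 + exp((ex - 405) / 12))
  crv <- structure(data.frame(x = ex, ex_ev = rev(ex), em_ev = em,
                              ex_nm = ex, em_nm = em),
                   class = c("rees_curve", "data.frame"))
  s <- summarize_curve(crv)
  expect_equal(s$midpoint_ex_nm, 405, tolerance = 0.01)
  expect_equal(s$midpoint_slope, 20 / (4 * 12), tolerance = 1e-3)
})

test_that("steeper free-energy gradients move the transition red", {
  lig <- sim_ligand()
  # linear ramp family
  mids_lin <- vapply(c(0.0025, 0.005, 0.01, 0.02, 0.05), function(a)
    summarize_curve(simulate_rees_curve(lig, fel_spec(a, 1, 0.1, 10)))$
      midpoint_ex_nm, numeric(1))
  expect_true(all(diff(mids_lin) > 0))
  # quadratic family: mid-point shifts red and the transition flattens
  qs <- lapply(c(0.001, 0.002, 0.005, 0.01), function(a)
    summarize_curve(simulate_rees_curve(lig, fel_spec(a, 2, 0.15, 10))))
  expect_true(all(diff(vapply(qs, `[[`, numeric(1), "midpoint_ex_nm")) > 0))
  expect_true(all(diff(vapply(qs, `[[`, numeric(1), "midpoint_slope")) < 0))
})

test_that("wider microstate spacing steepens the transition while spacing
           stays below the thermal coordinate width", {
  lig <- sim_ligand()
  sl_lin <- vapply(c(0.02, 0.04, 0.06), function(xg)
    summarize_curve(simulate_rees_curve(lig, fel_spec(0.0025, 1, xg, 10)))$
      midpoint_slope, numeric(1))
  expect_true(all(diff(sl_lin) > 0))
  sl_quad <- vapply(c(0.01, 0.02, 0.05, 0.1), function(xg)
    summarize_curve(simulate_rees_curve(lig, fel_spec(0.0025, 2, xg, 10)))$
      midpoint_slope, numeric(1))
  expect_true(all(diff(sl_quad) > 0))
})

test_that("more microstates shift the mid-point red and flatten the slope", {
  lig <- sim_ligand()
  s <- lapply(c(5, 10, 15, 20), function(m)
    summarize_curve(simulate_rees_curve(lig, fel_spec(0.0025, 2, 0.15, m))))
  mids <- vapply(s, `[[`, numeric(1), "midpoint_ex_nm")
  slopes <- vapply(s, `[[`, numeric(1), "midpoint_slope")
  # the sweep window truncates the largest landscape, so the red shift is
  # asserted where the window covers the states
  expect_true(all(diff(mids[1:3]) > 0))
  expect_true(all(diff(slopes) < 0))
})

test_that("curve resampling and CSV export round-trip", {
  crv <- simulate_rees_curve(p38a_ligand(), p38a_fel())
  g <- seq(350, 550, length.out = 7)
  em <- resample_curve(crv, g)
  expect_length(em, 7)
  expect_true(all(diff(em) > 0))
  expect_error(resample_curve(crv, 10), "outside")
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(crv, path)
  back <- read_rees_csv(path)
  expect_equal(nrow(back), nrow(crv))
  expect_equal(back$em_nm, sort(crv$em_nm), tolerance = 1e-6)
})
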