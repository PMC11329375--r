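test_that("Na+ influx follows the hand unit chain", {
  expect_equal(na_flux_per_cell(0, 20), 0)
  # 0.31 pA/pF x 20 pF = 6.2 pA; / F = 6.43e-17 mol/s (independent chain)
  oracle <- 0.31 * 20 * 1e-12 / 96485.332
  expect_equal(na_flux_per_cell(-0.31, 20), oracle, tolerance = 1e-12)
  expect_equal(oracle, 6.43e-17, tolerance = 5e-3)
  expect_equal(na_flux_per_cell(-0.62, 20),
               2 * na_flux_per_cell(-0.31, 20))  # linearity
  expect_error(na_flux_per_cell(NaN, 20), "finite")
  expect_error(na_flux_per_cell(-0.31, 0), "> 0")
})

test_that("the stoichiometric chain reproduces the published prediction", {
  pred <- predict_ecar(-0.31, 20)
  expect_equal(pred$ecar_mpH_min, 1.3, tolerance = 0.02)
  expect_equal(predict_ecar(0.0001, 20)$ecar_mpH_min, 0, tolerance = 1e-3)
  # and the prediction sits within an order of magnitude of the measured
  # TTX effect
  oom <- order_of_magnitude_check(pred$ecar_mpH_min, 9.8)
  expect_true(oom$pass)
})

test_that("flux conservation holds at every prediction", {
  set.seed(31)
  for (i in 1:20) {
    st <- stoichiometry_params(na_per_atp = sample(2:4, 1),
                               atp_per_glucose = 2,
                               lactate_per_glucose = sample(1:3, 1))
    p <- predict_ecar(-runif(1, 0.05, 1), runif(1, 5, 40), stoich = st)
    expect_equal(p$h_flux_mol_s_cell * st$na_per_atp,
                 p$na_flux_mol_s_cell * st$h_per_atp, tolerance = 1e-12)
    expect_equal(p$atp_flux_mol_s_cell,
                 p$na_flux_mol_s_cell / st$na_per_atp, tolerance = 1e-12)
  }
})

test_that("predicted ECAR scales as dimensional analysis dictates", {
  base <- predict_ecar(-0.31, 20)$ecar_mpH_min
  expect_equal(predict_ecar(-0.62, 20)$ecar_mpH_min, 2 * base)
  expect_equal(predict_ecar(-0.31, 40)$ecar_mpH_min, 2 * base)
  w <- well_geometry()
  dbl_cells <- well_geometry(cells_per_well = 2 * w$cells_per_well)
  dbl_vol <- well_geometry(volume_l = 2 * w$volume_l)
  dbl_buf <- well_geometry(buffering_power_mol_l_ph =
                             2 * w$buffering_power_mol_l_ph)
  expect_equal(predict_ecar(-0.31, 20, well = dbl_cells)$ecar_mpH_min,
               2 * base)
  expect_equal(predict_ecar(-0.31, 20, well = dbl_vol)$ecar_mpH_min,
               base / 2)
  expect_equal(predict_ecar(-0.31, 20, well = dbl_buf)$ecar_mpH_min,
               base / 2)
  expect_error(well_geometry(buffering_power_mol_l_ph = 0), "> 0")
})

test_that("Seahorse generator honours its contract", {
  d0 <- simulate_seahorse(step_change_mpH_min = 0, noise_sd = 0,
                          artefact_mpH_min = 0, seed = 1)
  eff0 <- measure_ecar_effect(d0)
  expect_equal(eff0$effect, 0)
  expect_error(simulate_seahorse(noise_sd = -1), ">= 0")
  expect_error(simulate_seahorse(injection_index = 16, n_timepoints = 16),
               "injection_index")
  # determinism
  expect_identical(simulate_seahorse(seed = 5), simulate_seahorse(seed = 5))
})

test_that("the last-6-timepoints estimator is exact without noise and
           unbiased with noise", {
  exact <- measure_ecar_effect(simulate_seahorse(
    step_change_mpH_min = -9.8, noise_sd = 0, artefact_mpH_min = 0,
    seed = 1))
  expect_equal(exact$effect, 9.8)
  # the injection artefact decays within its 15 min span, so it barely
  # leaks into the last-6 window
  with_art <- measure_ecar_effect(simulate_seahorse(
    step_change_mpH_min = -9.8, noise_sd = 0, seed = 1))
  expect_equal(with_art$effect, 9.8, tolerance = 1e-3)
  # Monte-Carlo oracle over repeated noisy plates
  effs <- vapply(1:200, function(s) {
    measure_ecar_effect(simulate_seahorse(noise_sd = 1.5,
                                          seed = 1000 + s))$effect
  }, numeric(1))
  mc_sem <- sd(effs) / sqrt(length(effs))
  expect_lt(abs(mean(effs) - 9.8), 3 * mc_sem)
  # single 3-plate experiment: within 2 SEM of truth
  one <- measure_ecar_effect(simulate_seahorse(n_plates = 3, noise_sd = 1.5,
                                               seed = 13))
  expect_lt(abs(one$effect - 9.8), 2 * one$sem + 3 * sd(effs) / sqrt(3))
})

test_that("the estimator refuses windows inside the artefact exclusion", {
  d <- simulate_seahorse(n_timepoints = 9, injection_index = 6, seed = 1)
  expect_error(measure_ecar_effect(d), "artefact")
  expect_error(measure_ecar_effect(data.frame(x = 1)), "columns")
})

test_that("order-of-magnitude check brackets its boundary", {
  expect_equal(order_of_magnitude_check(1.3, 9.8)$ratio, 9.8 / 1.3)
  expect_true(order_of_magnitude_check(1.3, 9.8)$pass)
  expect_true(order_of_magnitude_check(4, 4)$ratio == 1)
  expect_false(order_of_magnitude_check(1, 10.01)$pass)
  expect_true(order_of_magnitude_check(1, 10)$pass)
  expect_error(order_of_magnitude_check(-1, 5), "> 0")
})
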