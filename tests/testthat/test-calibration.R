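test_that("electrode line fit matches two-point algebra", {
  cal <- data.frame(index = 1:2, block = 1, type = "calibration",
                    known_ph = c(7, 8), voltage_mv = c(-30, -88))
  map <- fit_electrode(cal)
  expect_equal(map$slope_mv_per_ph, -58)
  expect_equal(invert_electrode(map, -59), 7.5)
  # perfectly collinear points give r^2 = 1
  cal3 <- data.frame(index = 1:3, block = 1, type = "calibration",
                     known_ph = 6:8, voltage_mv = 376 - 58 * (6:8))
  expect_equal(fit_electrode(cal3)$r_squared, 1)
  # adding a constant moves the intercept only
  shifted <- cal3; shifted$voltage_mv <- shifted$voltage_mv + 12
  m0 <- fit_electrode(cal3); m1 <- fit_electrode(shifted)
  expect_equal(m1$slope_mv_per_ph, m0$slope_mv_per_ph)
  expect_equal(m1$intercept_mv, m0$intercept_mv + 12)
  # rank-deficient calibration is rejected
  one_ph <- data.frame(index = 1:2, block = 1, type = "calibration",
                       known_ph = c(7, 7), voltage_mv = c(-30, -31))
  expect_error(fit_electrode(one_ph), "distinct pH")
  # both regression directions agree on a two-point line
  expect_equal(fit_electrode(cal, "ph_on_voltage")$slope_mv_per_ph, -58)
})

test_that("offset schedule corrects block-wise junction drift", {
  s0 <- simulate_electrode_series(rep(7, 24), offset_drift_mv_per_block = 0,
                                  noise_sd_mv = 0, seed = 1)
  expect_equal(apply_offset_schedule(s0)$voltage_mv, s0$voltage_mv)
  # uncorrected readings drift; corrected readings are constant
  s2 <- simulate_electrode_series(rep(7, 24), offset_drift_mv_per_block = 2,
                                  noise_sd_mv = 0, seed = 1)
  raw_ph <- (s2$voltage_mv[s2$type == "measurement"] - 376) / -58
  expect_gt(diff(range(raw_ph)), 0.02)
  res <- electrode_ph(s2)
  expect_equal(res$measurements$ph, rep(7, 24), tolerance = 1e-9)
  # a block without a bath reading is an orphan
  s_orph <- s2[s2$type != "bath" | s2$block != 2, ]
  expect_error(apply_offset_schedule(s_orph), "without an offset")
})

test_that("alternating two-region series is recovered by construction", {
  truth <- rep(c(7.0, 6.8), 12)
  s <- simulate_electrode_series(truth, offset_drift_mv_per_block = 2,
                                 noise_sd_mv = 0, seed = 2)
  res <- electrode_ph(s)
  rec <- res$measurements$ph
  expect_equal(mean(rec[seq(1, 24, by = 2)]), 7.0, tolerance = 1e-9)
  expect_equal(mean(rec[seq(2, 24, by = 2)]), 6.8, tolerance = 1e-9)
})

test_that("electrode round trip meets its noise tolerances", {
  truth <- runif(24, 6.5, 7.5)
  s0 <- simulate_electrode_series(truth, noise_sd_mv = 0, seed = 3)
  expect_lt(max(abs(electrode_ph(s0)$measurements$ph - truth)), 0.01)
  s1 <- simulate_electrode_series(truth, noise_sd_mv = 1, seed = 3)
  expect_lt(mean(abs(electrode_ph(s1)$measurements$ph - truth)), 0.05)
})

test_that("per-cell BCECF calibration is an interpolation identity", {
  expect_equal(bcecf_resting_ph(2, 3, 2.4)$per_cell, 7.4)
  expect_equal(bcecf_resting_ph(2, 3, 2)$per_cell, 7.0)
  # any monotone two-point line is inverted exactly
  set.seed(41)
  r7 <- runif(20, 1, 3); r8 <- r7 + runif(20, 0.5, 2)
  truth <- runif(20, 6, 8)
  resting <- r7 + (truth - 7) * (r8 - r7)
  expect_equal(bcecf_resting_ph(r7, r8, resting)$per_cell, truth)
  expect_error(bcecf_resting_ph(2, 2, 2.4), "degenerate")
  expect_error(bcecf_resting_ph(c(2, 2), 3, c(2.4, 2.5)), "equal length")
})

test_that("BCECF cohort recovers an acidified resting pH", {
  d <- simulate_bcecf_cells(n_cells = 40, true_ph = 6.3, seed = 6)
  res <- bcecf_resting_ph(d$ratio_at_7, d$ratio_at_8, d$resting_ratio)
  expect_equal(res$n, 40)
  expect_lt(abs(res$mean - 6.3), 2 * res$sem + 0.02)
})

test_that("SBFI fold change needs background subtraction to be unbiased", {
  p_id <- simulate_plate_fluorescence(true_ratio_fold = 1, noise_sd = 0,
                                      seed = 1)
  expect_equal(sbfi_fold_change(p_id)$fold, 1)
  p22 <- simulate_plate_fluorescence(true_ratio_fold = 2.2, noise_sd = 0,
                                     seed = 1)
  expect_equal(sbfi_fold_change(p22)$fold, 2.2)
  # algebraic oracle: the uncorrected ratio is biased toward 1
  p2 <- simulate_plate_fluorescence(true_ratio_fold = 2, noise_sd = 0,
                                    seed = 1)
  raw_ratio <- p2$f340 / p2$f380
  raw_fold <- mean(raw_ratio[p2$group == "treated"]) /
    mean(raw_ratio[p2$group == "vehicle"])
  expect_lt(raw_fold, 2)
  expect_gt(raw_fold, 1)
  expect_equal(sbfi_fold_change(p2)$fold, 2)
  # common-gain invariance across both wavelengths
  scaled <- p2; scaled$f340 <- 3 * scaled$f340; scaled$f380 <- 3 * scaled$f380
  expect_equal(sbfi_fold_change(scaled)$fold, 2)
  no_bg <- p2[p2$group != "background", ]
  expect_error(sbfi_fold_change(no_bg), "background")
})

test_that("repeat-level SBFI experiment recovers the generating fold", {
  res <- sbfi_repeats(n_repeats = 6, true_ratio_fold = 2.2, seed = 8)
  expect_equal(res$n_repeats, 6)
  expect_lt(abs(res$fold - 2.2), 2 * res$sem + 0.02)
})

test_that("slice-pH pipeline recovers both regional means", {
  res <- recover_slice_ph(n_slices = 9, seed = 9)
  expect_lt(abs(res$periphery$mean - 6.8), 2 * res$periphery$sem + 0.05)
  expect_lt(abs(res$core$mean - 7.0), 2 * res$core$sem + 0.05)
  expect_lt(res$periphery$mean, res$core$mean)
})
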