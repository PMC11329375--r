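test_that("the current-pH map honours its anchors and clamp", {
  fp <- feedback_params()
  expect_identical(current_vs_ph(fp, 7.2), -0.31)
  expect_identical(current_vs_ph(fp, 6.2), -0.71)
  expect_equal(current_vs_ph(fp, 6.7), mean(c(-0.31, -0.71)))  # linear
  expect_equal(current_vs_ph(fp, 5.8), current_vs_ph(fp, 6.0))  # clamp
  expect_equal(current_vs_ph(fp, 7.6), current_vs_ph(fp, 7.4))
  # monotone non-increasing over the physiological range, both map forms
  ph <- seq(6.0, 7.4, by = 0.05)
  expect_true(all(diff(current_vs_ph(fp, ph)) <= 0) ||
                all(diff(-current_vs_ph(fp, ph)) <= 0))
  expect_true(all(diff(abs(current_vs_ph(fp, ph))) <= 1e-12))
  fp_log <- feedback_params(map = "log_h")
  expect_equal(current_vs_ph(fp_log, 7.2), -0.31)
  expect_equal(current_vs_ph(fp_log, 6.2), -0.71)
  expect_true(all(diff(abs(current_vs_ph(fp_log, ph))) <= 1e-12))
})

test_that("steady state solves the loop's fixed-point equation", {
  fp0 <- feedback_params(gain = 0)
  expect_equal(feedback_steady_state(fp0)$ph_e, 7.4)  # feedback disabled
  fp <- feedback_params(gain = 1, relaxation_per_min = 0.01)
  ss <- feedback_steady_state(fp)
  expect_true(ss$converged)
  expect_lt(ss$ph_e, fp$ph_bath)  # acid source strictly positive
  # brute-force bisection oracle on the scalar equation
  g <- function(p) {
    dens <- current_vs_ph(fp, p)
    ecar <- predict_ecar(dens, fp$capacitance_pf, fp$stoich,
                         fp$well)$ecar_mpH_min
    fp$ph_bath - fp$gain * ecar / (1000 * fp$relaxation_per_min)
  }
  lo <- 5.5; hi <- 7.4
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) - mid > 0) lo <- mid else hi <- mid
  }
  expect_equal(ss$ph_e, (lo + hi) / 2, tolerance = 1e-9)
})

test_that("dynamics agree with the fixed point and converge in dt", {
  fp <- feedback_params(gain = 1, relaxation_per_min = 0.01)
  ss <- feedback_steady_state(fp)
  # starting at the steady state the trajectory stays flat
  flat <- feedback_dynamics(fp, ph0 = ss$ph_e, t_span = 50, dt = 0.5)
  expect_lt(max(abs(flat$ph_e - ss$ph_e)), 1e-8)
  # monotone approach for a scalar autonomous system
  traj <- feedback_dynamics(fp, ph0 = 7.4, t_span = 2500, dt = 0.5)
  expect_true(all(diff(traj$ph_e) <= 1e-12))
  expect_lt(abs(traj$ph_e[nrow(traj)] - ss$ph_e), 1e-6)
  # halving the step barely moves the terminal state
  half <- feedback_dynamics(fp, ph0 = 7.4, t_span = 2500, dt = 0.25)
  expect_lt(abs(half$ph_e[nrow(half)] - traj$ph_e[nrow(traj)]), 1e-6)
})

test_that("fixed point and dynamics agree across a parameter grid", {
  for (gain in c(0.5, 1, 2)) {
    for (relax in c(0.02, 0.05)) {
      # the loop slows the effective relaxation, so integrate well past
      # the open-loop time constant
      fp <- feedback_params(gain = gain, relaxation_per_min = relax)
      ss <- feedback_steady_state(fp)
      tr <- feedback_dynamics(fp, ph0 = fp$ph_bath,
                              t_span = 30 / relax, dt = 0.5)
      expect_lt(abs(tr$ph_e[nrow(tr)] - ss$ph_e), 1e-6)
    }
  }
})

test_that("comparative statics are monotone", {
  ph_by_gain <- vapply(c(0, 0.5, 1, 2, 4), function(g) {
    feedback_steady_state(feedback_params(gain = g))$ph_e
  }, numeric(1))
  expect_true(all(diff(ph_by_gain) <= 1e-12))  # non-increasing in gain
  ph_by_relax <- vapply(c(0.005, 0.01, 0.05, 0.2), function(r) {
    feedback_steady_state(feedback_params(relaxation_per_min = r))$ph_e
  }, numeric(1))
  expect_true(all(diff(ph_by_relax) >= -1e-12))  # non-decreasing in relax
})

test_that("feedback amplification reflects the loop's strength", {
  flat_map <- feedback_params(anchors = cbind(ph = c(7.2, 6.2),
                                              density = c(-0.31, -0.31)))
  expect_equal(feedback_amplification(flat_map)$amplification, 1,
               tolerance = 1e-6)
  fp <- feedback_params()
  amp <- feedback_amplification(fp)
  expect_gt(amp$amplification, 1)
  # a steeper current-pH map amplifies more
  steep <- feedback_params(anchors = cbind(ph = c(7.2, 6.2),
                                           density = c(-0.31, -1.1)))
  expect_gt(feedback_amplification(steep)$amplification,
            amp$amplification)
  expect_error(feedback_amplification(feedback_params(gain = 0)), "gain")
})

test_that("parameter validation guards the loop", {
  expect_error(feedback_params(relaxation_per_min = 0), "> 0")
  expect_error(feedback_params(gain = -1), ">= 0")
  expect_error(feedback_params(anchors = cbind(7.2, -0.31)), "two pH")
})
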