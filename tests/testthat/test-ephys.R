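test_that("P/6 subtraction removes an ohmic leak exactly", {
  # pure ohmic "cell": essentially zero channel conductance
  ch <- channel_model(gmax_density = 1e-9, act_v_half = -15.2, act_k = 10.7,
                      inact_v_half = -80.4, inact_k = -8.4)
  rec <- leak_subtract(simulate_recording(
    ch, cell_model(leak_conductance_ns = 2), make_activation_protocol(10),
    noise_model(0, 1)))
  expect_lt(max(abs(rec$sweeps)), 1e-5)
  # channel + leak equals the channel-only simulation after subtraction
  with_leak <- leak_subtract(simulate_recording(
    nav15_channel(7.2), cell_model(leak_conductance_ns = 3),
    make_activation_protocol(10), noise_model(0, 1)))
  no_leak <- leak_subtract(simulate_recording(
    nav15_channel(7.2), cell_model(leak_conductance_ns = 0),
    make_activation_protocol(10), noise_model(0, 1)))
  expect_equal(with_leak$sweeps, no_leak$sweeps, tolerance = 1e-9)
})

test_that("P/6 inflates noise variance 7-fold on a leak-only sweep", {
  # variance algebra: var(main - 6 * mean of 6 subs) = (1 + 36/6) sigma^2
  set.seed(11)
  n <- 20000
  sigma <- 1.3
  main <- rnorm(n, 0, sigma)
  subs <- matrix(rnorm(n * 6, 0, sigma), n, 6)
  corrected <- p6_leak_subtract(main, subs, scale = 1 / 6)
  expect_equal(mean(corrected), 0, tolerance = 0.05)
  expect_equal(var(corrected), 7 * sigma^2, tolerance = 0.05)
})

test_that("P/6 rejects malformed sub-sweep sets", {
  main <- rnorm(100)
  expect_error(p6_leak_subtract(main, matrix(0, 100, 5)), "6")
  expect_error(p6_leak_subtract(main, matrix(0, 99, 6)), "mismatched")
  expect_error(p6_leak_subtract(main, matrix(0, 100, 6), scale = 0),
               "nonzero")
})

test_that("half-peak-to-peak correction follows its stated arithmetic", {
  t <- seq(0, 60, by = 0.1)
  onset <- 20
  flat <- rep(-5, length(t))
  expect_equal(half_peak_noise_correct(flat, t, onset), flat)  # noiseless
  # square-wave baseline of amplitude +/- a subtracts exactly a
  a <- 0.8
  sq <- ifelse(t < onset, a * rep_len(c(1, -1), length(t)), -50)
  expect_equal(half_peak_noise_correct(sq, t, onset)[t >= onset],
               rep(-50 + a, sum(t >= onset)))
  expect_error(half_peak_noise_correct(flat, t, depol_onset_ms = 5,
                                       baseline_window = c(-20, 5)),
               "outside")
})

test_that("expected correction matches the Gaussian-range oracle", {
  # Monte-Carlo oracle: half the expected range of n standard normals
  set.seed(21)
  n <- 100; sigma <- 0.4; reps <- 400
  oracle <- mean(replicate(reps, diff(range(rnorm(n))))) / 2 * sigma
  t <- seq(0, 20, by = 10 / n)[1:(2 * n)]
  corr <- replicate(reps, {
    sweep <- c(rnorm(n, 0, sigma), rep(-30, n))
    half_peak_noise_correct(sweep, t, depol_onset_ms = 10)[n + 1] - (-30)
  })
  expect_equal(mean(corr), oracle, tolerance = 0.03)
})

test_that("plain-baseline correction mode subtracts the baseline mean", {
  t <- seq(0, 30, by = 0.1)
  sweep <- ifelse(t < 10, 2, -40)
  out <- half_peak_noise_correct(sweep, t, 10, mode = "baseline")
  expect_equal(out[t >= 10], rep(-42, sum(t >= 10)))
})

test_that("peak density picks the most negative current per step", {
  rec <- corrected(noiseless_recording(7.2, "activation"))
  iv <- peak_density(rec)
  expect_s3_class(iv, "iv_curve")
  expect_equal(min(iv$density_pa_pf), -13.5, tolerance = 0.02)
  # dense-grid oracle for the voltage of the peak: argmin of
  # m_inf(V) * (V - e_rev) over the protocol steps
  ch <- nav15_channel(7.2)
  steps <- protocol_steps(rec$protocol)
  oracle_v <- steps[which.min(boltzmann(steps, ch$act[["v_half"]],
                                        ch$act[["k"]]) *
                                (steps - ch$e_rev))]
  expect_equal(iv$voltage_mv[which.min(iv$density_pa_pf)], oracle_v)
  # all-zero sweeps give a zero curve
  zero <- flat_recording(level_pa = 0)
  expect_equal(peak_density(zero)$density_pa_pf, 0)
  # outward convention picks the most positive current
  expect_equal(peak_density(flat_recording(40),
                            direction = "outward")$density_pa_pf, 2)
})

test_that("persistent density is the late-window mean over capacitance", {
  # constant -10 pA plateau over a 20 pF cell: -0.5 pA/pF
  expect_equal(unname(persistent_density(flat_recording(-10, 20))), -0.5)
  short <- flat_recording(n_ms = 30, onset_ms = 10)
  expect_error(persistent_density(short, window_ms = c(20, 25)), "extend")
})

test_that("activation curve equals the activation gate of the generator", {
  rec <- corrected(noiseless_recording(7.2, "activation"))
  crv <- activation_curve(rec)
  expect_equal(max(crv$g_norm), 1)
  ch <- nav15_channel(7.2)
  m <- boltzmann(crv$voltage_mv, ch$act[["v_half"]], ch$act[["k"]])
  # max-normalized curve equals m_inf up to the normalization reference
  expect_equal(crv$g_norm, m / max(m), tolerance = 0.01)
  expect_error(activation_curve(rec, e_rev = 5), "outside")
})

test_that("inactivation curve equals the availability gate", {
  rec <- corrected(noiseless_recording(7.2, "inactivation"))
  crv <- inactivation_curve(rec)
  expect_equal(crv$response[crv$voltage_mv == -120], 1)  # reference
  ch <- nav15_channel(7.2)
  h <- boltzmann(crv$voltage_mv, ch$inact[["v_half"]], ch$inact[["k"]])
  expect_equal(crv$response, h / h[crv$voltage_mv == -120],
               tolerance = 0.005)
  # depolarised prepulse leaves ~no transient
  expect_lt(abs(crv$response[crv$voltage_mv == 30]), 0.01)
  expect_error(inactivation_curve(corrected(
    noiseless_recording(7.2, "activation"))), "inactivation protocol")
})

test_that("window current peaks between the two half-voltages and grows
           with the acid shift", {
  v <- seq(-120, 30, by = 1)
  f72a <- fit_boltzmann(v, boltzmann(v, -15.2, 10.7), "activation")
  f72i <- fit_boltzmann(v, boltzmann(v, -80.4, -8.4), "inactivation")
  f62a <- fit_boltzmann(v, boltzmann(v, -12.9, 9.5), "activation")
  f62i <- fit_boltzmann(v, boltzmann(v, -73.3, -11.9), "inactivation")
  w72 <- window_current(f72a, f72i)
  w62 <- window_current(f62a, f62i)
  expect_gt(w62$max, w72$max)  # acidification enlarges the window
  # calculus oracle: the product's maximum lies between the midpoints
  expect_gt(w72$v_max, -80.4); expect_lt(w72$v_max, -15.2)
  expect_gt(w62$v_max, -73.3); expect_lt(w62$v_max, -12.9)
  # near-step gates with disjoint transitions leave ~no window
  sharp_a <- fit_boltzmann(v, boltzmann(v, -10, 1), "activation")
  sharp_i <- fit_boltzmann(v, boltzmann(v, -90, -1), "inactivation")
  expect_lt(window_current(sharp_a, sharp_i)$max, 1e-8)
  expect_error(window_current(f72i, f72a), "activation")
})

test_that("availability is the per-cell mean of h at the resting potential", {
  v <- seq(-120, 30, by = 1)
  mid <- fit_boltzmann(v, boltzmann(v, -18.9, -8), "inactivation")
  expect_equal(availability_at(mid, -18.9)$fraction, 0.5, tolerance = 1e-6)
  # direct-formula oracle at the mean acidic-condition parameters:
  # 1 / (1 + exp(54.4 / 11.9))
  f62 <- fit_boltzmann(v, boltzmann(v, -73.3, -11.9), "inactivation")
  expect_equal(availability_at(f62, -18.9)$fraction,
               1 / (1 + exp(54.4 / 11.9)), tolerance = 1e-4)
  # the depolarising shift from pH 7.2 to 6.2 raises availability
  f72 <- fit_boltzmann(v, boltzmann(v, -80.4, -8.4), "inactivation")
  expect_gt(availability_at(f62)$fraction, availability_at(f72)$fraction)
  expect_equal(availability_at(list(f72, f62))$fraction,
               mean(c(availability_at(f72)$fraction,
                      availability_at(f62)$fraction)))
  expect_error(availability_at(list()), "no inactivation fits")
})

test_that("persistent density magnitude grows with the persistent fraction", {
  dens <- vapply(c(0.01, 0.03, 0.08), function(pf) {
    ch <- nav15_channel(7.2)
    ch$persistent_fraction <- pf
    rec <- leak_subtract(simulate_recording(
      ch, cell_model(), make_activation_protocol(10), noise_model(0, 1)))
    persistent_density(rec)[["0"]]
  }, numeric(1))
  expect_true(all(diff(abs(dens)) > 0))
})

test_that("the optional low-pass post-filter preserves slow components", {
  rec <- simulate_recording(nav15_channel(7.2), cell_model(),
                            make_activation_protocol(10),
                            noise_model(0.5, 5))
  filt <- postfilter(leak_subtract(rec), cutoff_khz = 1)
  expect_match(filt$corrections[length(filt$corrections)], "lowpass")
  # the persistent (slow) level survives filtering
  expect_equal(persistent_density(filt)[["0"]],
               persistent_density(leak_subtract(rec))[["0"]],
               tolerance = 0.02)
})
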