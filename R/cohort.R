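#' Synthetic validation cohorts and recovery estimators
#'
#' These functions generate cohorts of synthetic cells whose population
#' gating parameters equal the literature-anchored values of
#' [nav15_channel()], run the full analysis pipeline (P/6 leak
#' subtraction, conservative noise correction, I-V extraction, Boltzmann
#' fitting, window averaging) on each cell, and summarise how well the
#' estimators recover the generator truth.  Inter-cell scatter is kept
#' modest (see `cohort_jitter()`) so that estimator behaviour, not
#' biological variability, dominates the cohort mean.
#'
#' @param v_half_sd_mv SD of the additive jitter on both half-voltages,
#'   mV.
#' @param k_cv CV of the multiplicative jitter on both slope factors.
#' @param density_cv CV of the multiplicative jitter on the per-cell
#'   target peak and persistent current densities.
#' @param capacitance_sd_pf SD of the capacitance jitter around 20 pF.
#' @return `cohort_jitter()`: a list of jitter settings.
#' @export
cohort_jitter <- function(v_half_sd_mv = 1, k_cv = 0.05,
                          density_cv = 0.10, capacitance_sd_pf = 2) {
  list(v_half_sd_mv = v_half_sd_mv, k_cv = k_cv,
       density_cv = density_cv, capacitance_sd_pf = capacitance_sd_pf)
}

# one jittered cell: channel calibrated to jittered density targets
draw_cell <- function(ph_e, jitter, e_rev, tau_inact_ms) {
  ref <- nav15_reference_values(ph_e)
  ch <- channel_model(
    gmax_density = 1, e_rev = e_rev,
    act_v_half = ref[["act_v_half"]] + stats::rnorm(1, 0, jitter$v_half_sd_mv),
    act_k = ref[["act_k"]] * (1 + stats::rnorm(1, 0, jitter$k_cv)),
    inact_v_half = ref[["inact_v_half"]] +
      stats::rnorm(1, 0, jitter$v_half_sd_mv),
    inact_k = ref[["inact_k"]] * (1 + stats::rnorm(1, 0, jitter$k_cv)),
    tau_inact_ms = tau_inact_ms, persistent_fraction = 0
  )
  ch <- gmax_for_peak_density(
    ch, ref[["peak_density"]] * (1 + stats::rnorm(1, 0, jitter$density_cv)))
  ch <- persistent_fraction_for_density(
    ch, ref[["persistent_density"]] *
      (1 + stats::rnorm(1, 0, jitter$density_cv)))
  cm <- max(5, 20 + stats::rnorm(1, 0, jitter$capacitance_sd_pf))
  list(channel = ch, cell = cell_model(capacitance_pf = cm))
}

#' Simulate a cohort of cells under one or both gating protocols
#'
#' @param n_cells Number of cells.
#' @param ph_e Extracellular pH condition, 7.2 or 6.2.
#' @param protocols Which protocol recordings to generate per cell.
#' @param noise_sd Gaussian current noise SD, pA.
#' @param jitter Inter-cell scatter settings from [cohort_jitter()].
#' @param seed Integer seed; the cohort is fully reproducible.
#' @param e_rev,tau_inact_ms Shared biophysical settings.
#' @return List of per-cell lists with elements `channel`, `cell`, and a
#'   `vc_recording` per requested protocol (`$activation`,
#'   `$inactivation`).
#' @export
simulate_gating_cohort <- function(n_cells = 10, ph_e = 7.2,
                                   protocols = c("activation",
                                                 "inactivation"),
                                   noise_sd = 0.05,
                                   jitter = cohort_jitter(),
                                   seed = 1L,
                                   e_rev = nernst_potential(),
                                   tau_inact_ms = 1.5) {
  protocols <- match.arg(protocols, several.ok = TRUE)
  seed_stream(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  lapply(seq_len(n_cells), function(i) {
    seed_stream(cell_seeds[i])
    drawn <- draw_cell(as.character(ph_e), jitter, e_rev, tau_inact_ms)
    out <- drawn
    if ("activation" %in% protocols) {
      out$activation <- simulate_recording(
        drawn$channel, drawn$cell, make_activation_protocol(10),
        noise_model(sd_pa = noise_sd, seed = cell_seeds[i]),
        ph_e = as.numeric(ph_e), cell_id = sprintf("cell%02d", i))
    }
    if ("inactivation" %in% protocols) {
      out$inactivation <- simulate_recording(
        drawn$channel, drawn$cell, make_inactivation_protocol(10),
        noise_model(sd_pa = noise_sd, seed = cell_seeds[i] + 1L),
        ph_e = as.numeric(ph_e), cell_id = sprintf("cell%02d", i))
    }
    out
  })
}

# standard correction pipeline for one recording
correct_recording <- function(recording) {
  noise_correct(leak_subtract(recording), reference = "raw",
                mode = "magnitude")
}

#' Cohort recovery of the persistent current density
#'
#' Simulates `n_cells` under the activation protocol at the given pH
#' condition, applies the correction pipeline, and averages the
#' 20-25 ms window density at the persistent-current measurement step
#' (depolarisation to 0 mV).
#'
#' @inheritParams simulate_gating_cohort
#' @param step_mv Step at which the persistent current is read, mV.
#' @return List with `mean`, `sem`, `per_cell`, `truth` (the population
#'   target density), `n`.
#' @export
recover_persistent_cohort <- function(ph_e = 7.2, n_cells = 10, seed = 1L,
                                      noise_sd = 0.05, step_mv = 0,
                                      jitter = cohort_jitter()) {
  cohort <- simulate_gating_cohort(n_cells, ph_e, "activation",
                                   noise_sd, jitter, seed)
  per_cell <- vapply(cohort, function(cl) {
    rec <- correct_recording(cl$activation)
    dens <- persistent_density(rec)
    dens[[as.character(step_mv)]]
  }, numeric(1))
  truth <- nav15_reference_values(as.character(ph_e))[["persistent_density"]]
  list(mean = mean(per_cell), sem = stats::sd(per_cell) / sqrt(n_cells),
       per_cell = per_cell, truth = truth, n = n_cells)
}

#' Cohort recovery of the peak current density
#'
#' @inheritParams recover_persistent_cohort
#' @return List with `mean`, `sem`, `per_cell`, `truth`, `n`; the
#'   per-cell value is the most-negative peak density over the I-V curve.
#' @export
recover_peak_cohort <- function(ph_e = 7.2, n_cells = 11, seed = 1L,
                                noise_sd = 0.05, jitter = cohort_jitter()) {
  cohort <- simulate_gating_cohort(n_cells, ph_e, "activation",
                                   noise_sd, jitter, seed)
  per_cell <- vapply(cohort, function(cl) {
    iv <- peak_density(correct_recording(cl$activation))
    min(iv$density_pa_pf)
  }, numeric(1))
  truth <- nav15_reference_values(as.character(ph_e))[["peak_density"]]
  list(mean = mean(per_cell), sem = stats::sd(per_cell) / sqrt(n_cells),
       per_cell = per_cell, truth = truth, n = n_cells)
}

#' Cohort recovery of Boltzmann gating parameters
#'
#' Per cell, fits the activation curve (conductance transform of the peak
#' I-V) or the steady-state inactivation curve (normalized test-pulse
#' peaks) and reports cohort means of `v_half` and `k`.
#'
#' @inheritParams recover_persistent_cohort
#' @param kind `"activation"` or `"inactivation"`.
#' @param e_rev Reversal potential used in the conductance transform, mV.
#' @return List with `v_half` and `k` summaries (`mean`, `sem`,
#'   `per_cell`, `truth`), plus `n` and the per-cell fits.
#' @export
recover_gating_cohort <- function(ph_e = 7.2,
                                  kind = c("activation", "inactivation"),
                                  n_cells = 10, seed = 1L, noise_sd = 0.05,
                                  jitter = cohort_jitter(),
                                  e_rev = nernst_potential()) {
  kind <- match.arg(kind)
  cohort <- simulate_gating_cohort(n_cells, ph_e, kind, noise_sd, jitter,
                                   seed, e_rev = e_rev)
  fits <- lapply(cohort, function(cl) {
    rec <- correct_recording(cl[[kind]])
    if (kind == "activation") {
      crv <- activation_curve(rec, e_rev = e_rev)
      fit_boltzmann(crv$voltage_mv, crv$g_norm, "activation",
                    free_amplitude = TRUE)
    } else {
      crv <- inactivation_curve(rec)
      fit_boltzmann(crv$voltage_mv, crv$response, "inactivation",
                    free_amplitude = TRUE)
    }
  })
  ref <- nav15_reference_values(as.character(ph_e))
  truth <- if (kind == "activation") {
    c(v_half = ref[["act_v_half"]], k = ref[["act_k"]])
  } else {
    c(v_half = ref[["inact_v_half"]], k = ref[["inact_k"]])
  }
  vh <- vapply(fits, function(f) f$v_half_mv, numeric(1))
  kk <- vapply(fits, function(f) f$k_mv, numeric(1))
  list(
    v_half = list(mean = mean(vh), sem = stats::sd(vh) / sqrt(n_cells),
                  per_cell = vh, truth = unname(truth["v_half"])),
    k = list(mean = mean(kk), sem = stats::sd(kk) / sqrt(n_cells),
             per_cell = kk, truth = unname(truth["k"])),
    n = n_cells, fits = fits
  )
}
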