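#' P/6 leak subtraction
#'
#' Removes the linear (ohmic) leak component from a sweep using six
#' sub-amplitude leak records.  Each subsweep is driven by the command
#' waveform scaled by `scale` (1/6), so the summed scaled subsweeps -
#' equivalently `6 x mean(subsweeps)` - estimate the main sweep's leak,
#' which is subtracted.  For an ideal ohmic leak and amplifier-zeroed
#' traces the linear component is removed exactly; the corrected trace
#' variance is 7x the single-sweep noise variance.
#'
#' @param main_sweep Numeric current trace, pA.
#' @param subsweeps Time x 6 matrix of leak records, time-aligned with the
#'   main sweep.
#' @param scale Sub-pulse amplitude ratio; 1/6 for depolarising subpulses,
#'   -1/6 for the (channel-sparing) hyperpolarising convention.
#' @param baseline_idx Optional logical index of pre-depolarisation
#'   samples.  When given, each subsweep and the main sweep are first
#'   referenced to their own baseline means (standard P/N processing when
#'   the leak pulses are delivered from a separate subsweep holding
#'   potential).
#' @return Corrected trace, pA.
#' @export
p6_leak_subtract <- function(main_sweep, subsweeps, scale = 1 / 6,
                             baseline_idx = NULL) {
  if (!is.matrix(subsweeps) || ncol(subsweeps) != 6L) {
    stop("`subsweeps` must be a time x 6 matrix (P/6 protocol)",
         call. = FALSE)
  }
  if (nrow(subsweeps) != length(main_sweep)) {
    stop("subsweeps and main sweep have mismatched lengths", call. = FALSE)
  }
  stop_if_not_scalar(scale, "scale")
  if (scale == 0) stop("`scale` must be nonzero", call. = FALSE)
  if (!is.null(baseline_idx)) {
    if (!any(baseline_idx)) stop("empty baseline index", call. = FALSE)
    main_sweep <- main_sweep - mean(main_sweep[baseline_idx])
    subsweeps <- sweep(subsweeps, 2L,
                       colMeans(subsweeps[baseline_idx, , drop = FALSE]))
  }
  # mean(sub)/scale = +/-6 * mean(sub) at the standard 1/6 amplitude
  main_sweep - rowMeans(subsweeps) / scale
}

#' Conservative half-peak-to-peak noise correction
#'
#' Subtracts half the peak-to-peak noise measured during the baseline
#' window before depolarisation from the whole trace, with the sign chosen
#' so that the apparent inward (negative) current magnitude is reduced - a
#' deliberately conservative convention for detecting small persistent
#' currents.  `mode = "baseline"` gives plain baseline-mean subtraction
#' instead.
#'
#' @param sweep Numeric current trace, pA.
#' @param time_ms Time base of the trace, ms.
#' @param depol_onset_ms Time of depolarisation within the trace, ms.
#' @param baseline_window Window over which noise is measured, ms
#'   (default the 10 ms before depolarisation).
#' @param reference Trace from which the baseline noise is measured
#'   (default the sweep itself; pass the raw sweep to avoid measuring the
#'   P/6-inflated noise).
#' @param mode `"magnitude"` (half peak-to-peak, shifts inward current
#'   toward 0) or `"baseline"` (subtract the baseline mean).
#' @return Corrected trace, pA.
#' @export
half_peak_noise_correct <- function(sweep, time_ms, depol_onset_ms,
                                    baseline_window =
                                      c(depol_onset_ms - 10, depol_onset_ms),
                                    reference = sweep,
                                    mode = c("magnitude", "baseline")) {
  mode <- match.arg(mode)
  if (length(sweep) != length(time_ms) ||
      length(reference) != length(time_ms)) {
    stop("`sweep`, `reference` and `time_ms` must have equal length",
         call. = FALSE)
  }
  if (baseline_window[1] < min(time_ms) - 1e-9 ||
      baseline_window[2] > max(time_ms) + 1e-9 ||
      baseline_window[1] >= baseline_window[2]) {
    stop("baseline window lies outside the trace", call. = FALSE)
  }
  # strictly before depolarisation: the upper edge sample is excluded
  in_win <- time_ms >= baseline_window[1] - 1e-9 &
    time_ms < baseline_window[2] - 1e-9
  if (sum(in_win) < 2L) stop("baseline window contains < 2 samples",
                             call. = FALSE)
  base <- reference[in_win]
  if (mode == "baseline") return(sweep - mean(base))
  sweep + (max(base) - min(base)) / 2
}

#' Apply P/6 leak subtraction to every sweep of a recording
#'
#' Each sweep and its six leak records are referenced to their own
#' pre-depolarisation baselines and the scaled leak estimate is
#' subtracted, using the sub-pulse polarity the recording was generated
#' with.
#'
#' @param recording A `vc_recording` generated with `p6 = TRUE`.
#' @param per_trace_baseline Reference every trace to its own baseline
#'   mean first (default; required when the leak pulses come from a
#'   separate subsweep holding potential).
#' @return The recording with leak-subtracted sweeps; the raw sweeps are
#'   kept in `$raw_sweeps` for noise-reference use.
#' @export
leak_subtract <- function(recording, per_trace_baseline = TRUE) {
  stopifnot(inherits(recording, "vc_recording"))
  if (is.null(recording$p6_sweeps)) {
    stop("recording carries no P/6 subsweeps", call. = FALSE)
  }
  out <- recording
  out$raw_sweeps <- recording$sweeps
  scale <- recording$p6_scale %||% (1 / 6)
  base_idx <- if (per_trace_baseline) {
    recording$time_ms < recording$depol_onset_ms - 1e-9
  } else NULL
  for (j in seq_len(ncol(recording$sweeps))) {
    out$sweeps[, j] <- p6_leak_subtract(recording$sweeps[, j],
                                        recording$p6_sweeps[[j]],
                                        scale = scale,
                                        baseline_idx = base_idx)
  }
  out$corrections <- c(recording$corrections, "p6_leak")
  out
}

#' Apply the noise correction to every sweep of a recording
#'
#' By default the peak-to-peak noise is measured on the raw
#' (pre-leak-subtraction) baseline of each sweep, since P/6 subtraction
#' inflates baseline noise variance 7-fold, and is applied to the current
#' (possibly leak-subtracted) sweeps.
#'
#' @param recording A `vc_recording`.
#' @param reference `"raw"` (default, if raw sweeps are stored) or
#'   `"current"`.
#' @inheritParams half_peak_noise_correct
#' @return The corrected recording.
#' @export
noise_correct <- function(recording, reference = c("raw", "current"),
                          mode = c("magnitude", "baseline")) {
  stopifnot(inherits(recording, "vc_recording"))
  reference <- match.arg(reference)
  mode <- match.arg(mode)
  refm <- if (reference == "raw" && !is.null(recording$raw_sweeps)) {
    recording$raw_sweeps
  } else {
    recording$sweeps
  }
  out <- recording
  for (j in seq_len(ncol(recording$sweeps))) {
    out$sweeps[, j] <- half_peak_noise_correct(
      recording$sweeps[, j], recording$time_ms, recording$depol_onset_ms,
      reference = refm[, j], mode = mode)
  }
  out$corrections <- c(recording$corrections, paste0("noise_", mode))
  out
}

#' Optional 4-pole Butterworth low-pass post-filter
#'
#' Zero-phase (forward-backward) filtering at `cutoff_khz`, emulating the
#' 1 kHz post-filtering used when hunting for small currents.  Off by
#' default in every pipeline; synthetic noise is already band-limited in
#' effect.
#'
#' @param recording A `vc_recording`.
#' @param cutoff_khz Cutoff frequency, kHz.
#' @return The filtered recording.
#' @export
postfilter <- function(recording, cutoff_khz = 1) {
  stopifnot(inherits(recording, "vc_recording"))
  stop_if_not_positive(cutoff_khz, "cutoff_khz")
  w <- cutoff_khz / (recording$protocol$sample_khz / 2)
  if (w >= 1) stop("cutoff must be below the Nyquist frequency",
                   call. = FALSE)
  bf <- signal::butter(4, w, type = "low")
  out <- recording
  for (j in seq_len(ncol(recording$sweeps))) {
    out$sweeps[, j] <- signal::filtfilt(bf, recording$sweeps[, j])
  }
  out$corrections <- c(recording$corrections,
                       sprintf("lowpass_%gkHz", cutoff_khz))
  out
}

#' Peak current density I-V curve
#'
#' Per command step, the most-negative (inward) current within the search
#' window after depolarisation, divided by the cell capacitance.
#'
#' @param recording A (leak/noise-corrected) `vc_recording`.
#' @param window_ms Search window after depolarisation onset, ms.
#' @param direction `"inward"` (most negative) or `"outward"` (most
#'   positive, for K+ current families).
#' @return An object of class `iv_curve`: data.frame with `voltage_mv`
#'   and `density_pa_pf`.
#' @export
peak_density <- function(recording, window_ms = c(0, 10),
                         direction = c("inward", "outward")) {
  stopifnot(inherits(recording, "vc_recording"))
  direction <- match.arg(direction)
  if (recording$capacitance_pf <= 0) {
    stop("capacitance must be > 0", call. = FALSE)
  }
  t_rel <- recording$time_ms - recording$depol_onset_ms
  in_win <- t_rel >= window_ms[1] - 1e-9 & t_rel <= window_ms[2] + 1e-9
  if (!any(in_win)) stop("search window outside the trace", call. = FALSE)
  pick <- if (direction == "inward") {
    function(x) min(x)
  } else {
    function(x) max(x)
  }
  dens <- apply(recording$sweeps[in_win, , drop = FALSE], 2, pick) /
    recording$capacitance_pf
  out <- data.frame(voltage_mv = recording$command_mv,
                    density_pa_pf = unname(dens))
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' @export
plot.iv_curve <- function(x, ...) {
  plot(x$voltage_mv, x$density_pa_pf, type = "b",
       xlab = "Voltage (mV)", ylab = "Current density (pA/pF)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Persistent current density over a late window
#'
#' Mean current between `window_ms` (default 20-25 ms, closed interval on
#' the sampling grid) after depolarisation, divided by capacitance, per
#' sweep.
#'
#' @param recording A (corrected) `vc_recording`.
#' @param window_ms Averaging window after depolarisation onset, ms.
#' @return Named numeric vector of densities (pA/pF), one per command
#'   step.
#' @export
persistent_density <- function(recording, window_ms = c(20, 25)) {
  stopifnot(inherits(recording, "vc_recording"))
  t_rel <- recording$time_ms - recording$depol_onset_ms
  if (max(t_rel) < window_ms[2] - 1e-9) {
    stop("trace must extend at least to the end of the persistent window",
         call. = FALSE)
  }
  in_win <- t_rel >= window_ms[1] - 1e-9 & t_rel <= window_ms[2] + 1e-9
  dens <- colMeans(recording$sweeps[in_win, , drop = FALSE]) /
    recording$capacitance_pf
  names(dens) <- as.character(recording$command_mv)
  dens
}

#' Normalized conductance-voltage (activation) curve
#'
#' Transforms a peak I-V curve to conductance `G(V) = I_peak / (V - e_rev)`
#' and normalizes to the maximum.
#'
#' @param recording A corrected activation-protocol `vc_recording`.
#' @param e_rev Reversal potential used for the transform, mV; must lie
#'   outside the voltage range of the peaks used.
#' @param window_ms Peak search window, ms after depolarisation.
#' @return data.frame with `voltage_mv` and `g_norm`.
#' @export
activation_curve <- function(recording, e_rev = nernst_potential(),
                             window_ms = c(0, 10)) {
  iv <- peak_density(recording, window_ms = window_ms)
  if (any(abs(iv$voltage_mv - e_rev) < 1e-6)) {
    stop("a command step equals `e_rev`: conductance undefined there",
         call. = FALSE)
  }
  if (e_rev > min(iv$voltage_mv) && e_rev < max(iv$voltage_mv)) {
    stop("`e_rev` must lie outside the voltage range of the peaks used",
         call. = FALSE)
  }
  g <- iv$density_pa_pf / (iv$voltage_mv - e_rev)
  data.frame(voltage_mv = iv$voltage_mv, g_norm = g / max(g))
}

#' Normalized steady-state inactivation (availability) curve
#'
#' Test-pulse current per conditioning prepulse, normalized to the most
#' hyperpolarised (-120 mV) prepulse, which gives full availability.
#'
#' With `measure = "transient"` (default) the per-sweep value is the peak
#' minus the sustained level late in the same test pulse, so the
#' non-inactivating (persistent) component - which carries no
#' availability information and would otherwise put a floor under the
#' curve - cancels exactly.  `measure = "peak"` uses the raw test-pulse
#' peak.
#'
#' @param recording A corrected inactivation-protocol `vc_recording`.
#' @param window_ms Peak search window after the test-pulse onset, ms.
#' @param sustained_ms Late window whose mean defines the sustained level
#'   for the transient measure, ms after onset.
#' @param measure `"transient"` or `"peak"`.
#' @return data.frame with `voltage_mv` (prepulse) and `response`.
#' @export
inactivation_curve <- function(recording, window_ms = c(0, 10),
                               sustained_ms = c(20, 25),
                               measure = c("transient", "peak")) {
  stopifnot(inherits(recording, "vc_recording"))
  measure <- match.arg(measure)
  if (recording$protocol$kind != "inactivation") {
    stop("recording was not made with the inactivation protocol",
         call. = FALSE)
  }
  iv <- peak_density(recording, window_ms = window_ms)
  val <- iv$density_pa_pf
  if (measure == "transient") {
    val <- val - persistent_density(recording, window_ms = sustained_ms)
  }
  ref <- which(abs(iv$voltage_mv - (-120)) < 1e-6)
  if (length(ref) != 1L) {
    stop("missing -120 mV reference prepulse", call. = FALSE)
  }
  data.frame(voltage_mv = iv$voltage_mv,
             response = unname(val / val[ref]))
}

#' Window current: overlap of activation and availability curves
#'
#' Pointwise product `m_inf(V) * h_inf(V)` of one fitted activation and one
#' fitted inactivation Boltzmann on a voltage grid; the steady-state open
#' probability profile that permits sustained Na+ influx.
#'
#' @param act,inact `boltzmann_fit` objects of kind activation and
#'   inactivation respectively.
#' @param voltage_grid Evaluation grid, mV.
#' @return An object of class `window_current`: list with `voltage_mv`,
#'   `overlap`, `v_max` (grid argmax) and `max`.
#' @export
window_current <- function(act, inact,
                           voltage_grid = seq(-100, 20, by = 0.1)) {
  if (!inherits(act, "boltzmann_fit") || act$kind != "activation") {
    stop("`act` must be an activation boltzmann_fit", call. = FALSE)
  }
  if (!inherits(inact, "boltzmann_fit") || inact$kind != "inactivation") {
    stop("`inact` must be an inactivation boltzmann_fit", call. = FALSE)
  }
  ov <- predict(act, voltage_grid) * predict(inact, voltage_grid)
  i <- which.max(ov)
  structure(list(voltage_mv = voltage_grid, overlap = ov,
                 v_max = voltage_grid[i], max = ov[i]),
            class = "window_current")
}

#' @export
print.window_current <- function(x, ...) {
  cat(sprintf("Window current: max overlap %.4g at %.1f mV\n",
              x$max, x$v_max))
  invisible(x)
}

#' @export
plot.window_current <- function(x, ...) {
  plot(x$voltage_mv, x$overlap, type = "l", xlab = "Voltage (mV)",
       ylab = expression(m[infinity] %*% h[infinity]), ...)
  graphics::abline(v = x$v_max, lty = 3)
  invisible(x)
}

#' Channel availability at a membrane potential
#'
#' Fraction of channels not inactivated at `vm_mv`, evaluated per cell
#' from that cell's fitted inactivation curve (`h_inf(vm)`), then averaged
#' over cells.  The default potential is the reported resting membrane
#' potential of MDA-MB-231 cells, -18.9 mV.
#'
#' @param inact_fits A `boltzmann_fit` of kind inactivation, or a list of
#'   them (one per cell).
#' @param vm_mv Membrane potential, mV.
#' @return List with `vm_mv`, `fraction` (mean over cells) and `per_cell`.
#' @export
availability_at <- function(inact_fits, vm_mv = -18.9) {
  if (inherits(inact_fits, "boltzmann_fit")) inact_fits <- list(inact_fits)
  if (!length(inact_fits)) stop("no inactivation fits given", call. = FALSE)
  ok <- vapply(inact_fits, function(f) {
    inherits(f, "boltzmann_fit") && f$kind == "inactivation"
  }, logical(1))
  if (!all(ok)) stop("all elements must be inactivation fits", call. = FALSE)
  per_cell <- vapply(inact_fits, function(f) predict(f, vm_mv), numeric(1))
  list(vm_mv = vm_mv, fraction = mean(per_cell), per_cell = per_cell)
}
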