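#' Ground-truth channel, cell and noise models for the synthetic generator
#'
#' `channel_model()` declares the gating ground truth of a
#' Hodgkin-Huxley-style Na+ conductance with an instantaneously activating
#' gate (`m = m_inf(V)`), a first-order inactivation gate with time constant
#' `tau_inact_ms`, and a non-inactivating (persistent) fraction of the
#' conductance.  `cell_model()` declares passive membrane properties and
#' `noise_model()` the Gaussian recording noise.
#'
#' @param gmax_density Maximal conductance density, nS/pF (> 0).
#' @param e_rev Na+ reversal potential, mV.  The default is the Nernst
#'   potential for the recording solutions used with carcinoma cell lines
#'   (149 mM extracellular Na+ including titration, 5 mM pipette Na+, 21 C).
#' @param act_v_half,act_k Activation Boltzmann parameters, mV (`act_k > 0`).
#' @param inact_v_half,inact_k Steady-state inactivation Boltzmann
#'   parameters, mV (`inact_k < 0` by convention).
#' @param tau_inact_ms Inactivation time constant, ms (> 0).
#' @param persistent_fraction Fraction of the conductance that never
#'   inactivates, in `[0, 1]`.
#' @return `channel_model()`: an object of class `nav_channel`.
#' @examples
#' ch <- nav15_channel(7.2)
#' ch$persistent_fraction  # ~2% of the conductance is persistent
#' @export
channel_model <- function(gmax_density, e_rev = nernst_potential(),
                          act_v_half, act_k,
                          inact_v_half, inact_k,
                          tau_inact_ms = 1.5,
                          persistent_fraction = 0) {
  stop_if_not_positive(gmax_density, "gmax_density")
  stop_if_not_scalar(e_rev, "e_rev")
  stop_if_not_scalar(act_v_half, "act_v_half")
  stop_if_not_scalar(inact_v_half, "inact_v_half")
  stop_if_not_positive(tau_inact_ms, "tau_inact_ms")
  stop_if_not_scalar(act_k, "act_k")
  stop_if_not_scalar(inact_k, "inact_k")
  if (act_k <= 0) stop("`act_k` must be > 0 (activation)", call. = FALSE)
  if (inact_k >= 0) stop("`inact_k` must be < 0 (inactivation)", call. = FALSE)
  stop_if_not_scalar(persistent_fraction, "persistent_fraction")
  if (persistent_fraction < 0 || persistent_fraction > 1) {
    stop("`persistent_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    gmax_density = gmax_density, e_rev = e_rev,
    act = c(v_half = act_v_half, k = act_k),
    inact = c(v_half = inact_v_half, k = inact_k),
    tau_inact_ms = tau_inact_ms,
    persistent_fraction = persistent_fraction
  ), class = "nav_channel")
}

#' @rdname channel_model
#' @param capacitance_pf Membrane capacitance, pF (> 0; 20 pF default,
#'   typical of the carcinoma lines the generator emulates).
#' @param leak_conductance_ns Linear leak conductance, nS (>= 0).
#' @param leak_reversal_mv Leak reversal potential, mV.  Emitted sweeps are
#'   amplifier-zeroed at the holding level, so this only affects the
#'   (removed) holding current.
#' @return `cell_model()`: an object of class `nav_cell`.
#' @export
cell_model <- function(capacitance_pf = 20, leak_conductance_ns = 1,
                       leak_reversal_mv = 0) {
  stop_if_not_positive(capacitance_pf, "capacitance_pf")
  stop_if_negative(leak_conductance_ns, "leak_conductance_ns")
  stop_if_not_scalar(leak_reversal_mv, "leak_reversal_mv")
  structure(list(
    capacitance_pf = capacitance_pf,
    leak_conductance_ns = leak_conductance_ns,
    leak_reversal_mv = leak_reversal_mv
  ), class = "nav_cell")
}

#' @rdname channel_model
#' @param sd_pa Gaussian current-noise standard deviation, pA (>= 0),
#'   representing the effective post-filter baseline noise of the
#'   recording.
#' @param seed Integer random seed.
#' @return `noise_model()`: an object of class `nav_noise`.
#' @export
noise_model <- function(sd_pa = 0.05, seed = 1L) {
  stop_if_negative(sd_pa, "sd_pa")
  stop_if_not_scalar(seed, "seed")
  structure(list(sd_pa = sd_pa, seed = as.integer(seed)),
            class = "nav_noise")
}

#' Nernst equilibrium potential
#'
#' @param conc_out,conc_in Extracellular and intracellular ion
#'   concentrations, mM.
#' @param temp_c Temperature, degrees Celsius.
#' @param z Ion valence.
#' @return Potential in mV.
#' @examples
#' nernst_potential()  # ~ +86 mV for the default Na+ solutions
#' @export
nernst_potential <- function(conc_out = 149, conc_in = 5, temp_c = 21, z = 1) {
  stop_if_not_positive(conc_out, "conc_out")
  stop_if_not_positive(conc_in, "conc_in")
  R <- 8.31446; FARADAY <- 96485.332
  1000 * R * (temp_c + 273.15) / (z * FARADAY) * log(conc_out / conc_in)
}

# gating helpers on a channel
m_inf <- function(channel, v) {
  boltzmann(v, channel$act[["v_half"]], channel$act[["k"]])
}
h_inf <- function(channel, v) {
  boltzmann(v, channel$inact[["v_half"]], channel$inact[["k"]])
}

# noiseless current density (pA/pF) at voltage v and inactivation state h
density_at <- function(channel, v, h) {
  channel$gmax_density * m_inf(channel, v) *
    (channel$persistent_fraction + (1 - channel$persistent_fraction) * h) *
    (v - channel$e_rev)
}

#' Closed-form calibration of the generator to target current densities
#'
#' `gmax_for_peak_density()` inverts the noiseless forward model for the
#' maximal conductance density that makes the most-negative instantaneous
#' peak over the activation-protocol steps equal `peak_density_pa_pf`.
#' At the moment of depolarisation the inactivation gate still sits at its
#' holding steady state, so the continuous-time peak at step `V` is
#' `gmax * m_inf(V) * (pf + (1 - pf) * h_inf(holding)) * (V - e_rev)`.
#'
#' `persistent_fraction_for_density()` inverts the window-mean of the
#' forward model at the persistent-current measurement step for the
#' persistent fraction that makes the mean density over the
#' `[20, 25]` ms window equal `persistent_density_pa_pf`.
#'
#' Both inversions work on the amplifier-zeroed current - the forward
#' model minus the standing channel current at the holding potential -
#' because that is the quantity a whole-cell measurement reports; the
#' single-Boltzmann activation foot leaves a small standing current at
#' -120 mV that a real trace's zero offset absorbs.
#'
#' @param channel A `nav_channel` (its `gmax_density` /
#'   `persistent_fraction` is replaced by the calibrated value).
#' @param peak_density_pa_pf,persistent_density_pa_pf Target densities,
#'   pA/pF (negative for inward current).
#' @param protocol Activation protocol supplying the step grid and holding
#'   level.
#' @param step_mv Step at which the persistent current is measured, mV.
#' @param window_ms Persistent-current averaging window after
#'   depolarisation, ms.
#' @return A recalibrated `nav_channel`.
#' @export
gmax_for_peak_density <- function(channel, peak_density_pa_pf,
                                  protocol = make_activation_protocol(10)) {
  stopifnot(inherits(channel, "nav_channel"))
  stop_if_not_scalar(peak_density_pa_pf, "peak_density_pa_pf")
  if (peak_density_pa_pf >= 0) {
    stop("`peak_density_pa_pf` must be negative (inward current)",
         call. = FALSE)
  }
  steps <- protocol_steps(protocol)
  vh <- protocol$holding_mv
  h0 <- h_inf(channel, vh)
  pf <- channel$persistent_fraction
  standing <- m_inf(channel, vh) * (pf + (1 - pf) * h0) *
    (vh - channel$e_rev)
  per_unit <- m_inf(channel, steps) * (pf + (1 - pf) * h0) *
    (steps - channel$e_rev) - standing
  channel$gmax_density <- peak_density_pa_pf / min(per_unit)
  channel
}

#' @rdname gmax_for_peak_density
#' @export
persistent_fraction_for_density <- function(channel, persistent_density_pa_pf,
                                            step_mv = 0,
                                            window_ms = c(20, 25),
                                            protocol = make_activation_protocol(10)) {
  stopifnot(inherits(channel, "nav_channel"))
  stop_if_not_scalar(persistent_density_pa_pf, "persistent_density_pa_pf")
  # window-mean of h(t) = h_inf + (h0 - h_inf) exp(-t / tau)
  vh <- protocol$holding_mv
  h0 <- h_inf(channel, vh)
  hs <- h_inf(channel, step_mv)
  tau <- channel$tau_inact_ms
  w <- diff(window_ms)
  hbar <- hs + (h0 - hs) * tau / w *
    (exp(-window_ms[1] / tau) - exp(-window_ms[2] / tau))
  # zeroed density, linear in pf:
  #   gmax * [A (pf + (1-pf) hbar) - B (pf + (1-pf) h0)]
  a <- m_inf(channel, step_mv) * (step_mv - channel$e_rev)
  b <- m_inf(channel, vh) * (vh - channel$e_rev)
  t_unit <- persistent_density_pa_pf / channel$gmax_density
  pf <- (t_unit - (a * hbar - b * h0)) /
    (a - b - a * hbar + b * h0)
  if (!is.finite(pf) || pf < 0 || pf > 1) {
    stop(sprintf(
      "target density %.3g pA/pF is not reachable (implied fraction %.3g)",
      persistent_density_pa_pf, pf), call. = FALSE)
  }
  channel$persistent_fraction <- pf
  channel
}

#' Literature-anchored Na_v1.5 channel parameter sets
#'
#' Returns a `nav_channel` whose gating parameters equal the published
#' whole-cell means for MDA-MB-231 cells at extracellular pH 7.2 or 6.2
#' (activation v_half/k: -15.2/10.7 and -12.9/9.5 mV; inactivation
#' v_half/k: -80.4/-8.4 and -73.3/-11.9 mV), with the maximal conductance
#' and persistent fraction calibrated by closed-form inversion so that the
#' noiseless forward model reproduces the corresponding peak
#' (-13.5 / -9.6 pA/pF) and persistent (-0.31 / -0.71 pA/pF) current
#' densities.
#'
#' @param ph_e Extracellular pH condition: 7.2 or 6.2.
#' @param tau_inact_ms Inactivation time constant, ms.
#' @param e_rev Reversal potential, mV.
#' @return A calibrated `nav_channel`.
#' @export
nav15_channel <- function(ph_e = c(7.2, 6.2), tau_inact_ms = 1.5,
                          e_rev = nernst_potential()) {
  ph_e <- match.arg(as.character(ph_e[1L]), c("7.2", "6.2"))
  pars <- nav15_reference_values(ph_e)
  ch <- channel_model(
    gmax_density = 1, e_rev = e_rev,
    act_v_half = pars[["act_v_half"]], act_k = pars[["act_k"]],
    inact_v_half = pars[["inact_v_half"]], inact_k = pars[["inact_k"]],
    tau_inact_ms = tau_inact_ms, persistent_fraction = 0
  )
  ch <- gmax_for_peak_density(ch, pars[["peak_density"]])
  persistent_fraction_for_density(ch, pars[["persistent_density"]])
}

#' @rdname nav15_channel
#' @export
nav15_reference_values <- function(ph_e = c("7.2", "6.2")) {
  ph_e <- match.arg(as.character(ph_e[1L]), c("7.2", "6.2"))
  if (ph_e == "7.2") {
    c(peak_density = -13.5, persistent_density = -0.31,
      act_v_half = -15.2, act_k = 10.7,
      inact_v_half = -80.4, inact_k = -8.4)
  } else {
    c(peak_density = -9.6, persistent_density = -0.71,
      act_v_half = -12.9, act_k = 9.5,
      inact_v_half = -73.3, inact_k = -11.9)
  }
}

#' @export
print.nav_channel <- function(x, ...) {
  cat("Na+ channel ground truth\n")
  cat(sprintf("  gmax %.4g nS/pF, e_rev %.1f mV, tau_inact %.2g ms\n",
              x$gmax_density, x$e_rev, x$tau_inact_ms))
  cat(sprintf("  activation   v_half %.1f mV, k %.1f mV\n",
              x$act[["v_half"]], x$act[["k"]]))
  cat(sprintf("  inactivation v_half %.1f mV, k %.1f mV\n",
              x$inact[["v_half"]], x$inact[["k"]]))
  cat(sprintf("  persistent fraction %.4g\n", x$persistent_fraction))
  invisible(x)
}
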