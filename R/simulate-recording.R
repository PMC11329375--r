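#' Simulate a whole-cell voltage-clamp recording
#'
#' Forward model for a sweep family under either gating protocol.  Per
#' command step `V` the current is
#' `I(t) = gmax * Cm * m_inf(V) * (pf + (1 - pf) * h(t)) * (V - e_rev)
#'        + leak + noise`,
#' with `m_inf`, `h_inf` the Boltzmann forms of the channel's activation
#' and inactivation parameters, the activation gate instantaneous, and `h`
#' relaxing exponentially with `tau_inact_ms` from its pre-step steady
#' state.  Sweeps are amplifier-zeroed at the holding level (the steady
#' holding current is subtracted), which is the convention under which P/6
#' subtraction removes an ohmic leak exactly.
#'
#' Each emitted trace carries `baseline_ms` of pre-depolarisation baseline
#' (at the holding level for the activation protocol, at the tail of the
#' conditioning prepulse for the inactivation protocol) followed by the
#' test pulse.  When `p6 = TRUE`, six sub-amplitude leak sweeps (command
#' waveform scaled by 1/6 from holding) are generated per main sweep for
#' P/6 leak subtraction.
#'
#' @param channel A [channel_model()] ground truth.
#' @param cell A [cell_model()].
#' @param protocol A [make_activation_protocol()] or
#'   [make_inactivation_protocol()] specification.
#' @param noise A [noise_model()]; the seed makes sweeps reproducible.
#' @param p6 Generate P/6 leak subsweeps alongside each main sweep.
#' @param p6_polarity `-1` (default) delivers the 1/6-amplitude leak
#'   pulses in the hyperpolarising direction, where the channel stays
#'   shut - the standard choice for Na+ currents, since depolarising
#'   subpulses would activate window current and contaminate the leak
#'   estimate.  `+1` gives depolarising subpulses.
#' @param p6_holding_mv Subsweep holding potential from which the scaled
#'   leak pulses are delivered (default -150 mV, negative enough that no
#'   sub-command voltage carries channel current).
#' @param ph_e,cell_id Optional metadata carried in the recording.
#' @return An object of class `vc_recording`: list with `time_ms`,
#'   `sweeps` (time x step current matrix, pA), `command_mv`,
#'   `capacitance_pf`, `depol_onset_ms`, `protocol`, `p6_sweeps`
#'   (list of time x 6 matrices or `NULL`), `meta`, `corrections`.
#' @examples
#' rec <- simulate_recording(nav15_channel(7.2), cell_model(),
#'                           make_activation_protocol(10),
#'                           noise_model(sd_pa = 0, seed = 1))
#' dim(rec$sweeps)
#' @export
simulate_recording <- function(channel, cell, protocol,
                               noise = noise_model(),
                               p6 = TRUE, p6_polarity = -1,
                               p6_holding_mv = -150,
                               ph_e = NA_real_,
                               cell_id = NA_character_) {
  if (!p6_polarity %in% c(-1, 1)) {
    stop("`p6_polarity` must be -1 or +1", call. = FALSE)
  }
  if (!inherits(channel, "nav_channel")) {
    stop("`channel` must be a channel_model() (unit-consistent nS/pF, mV, ms)",
         call. = FALSE)
  }
  if (!inherits(cell, "nav_cell")) {
    stop("`cell` must be a cell_model()", call. = FALSE)
  }
  if (!inherits(protocol, "vc_protocol")) {
    stop("`protocol` must come from make_activation_protocol() or ",
         "make_inactivation_protocol()", call. = FALSE)
  }
  if (!inherits(noise, "nav_noise")) {
    stop("`noise` must be a noise_model()", call. = FALSE)
  }

  dt <- 1 / protocol$sample_khz
  n_base <- round(protocol$baseline_ms * protocol$sample_khz)
  n_test <- round(protocol$test_ms * protocol$sample_khz)
  time_ms <- seq(0, by = dt, length.out = n_base + n_test + 1L)
  onset <- n_base * dt
  steps <- protocol_steps(protocol)

  seed_stream(noise$seed)
  det <- function(v_pre, v_step, h_path) {
    # deterministic zeroed trace for a baseline/test voltage pair
    i_hold <- cell$capacitance_pf *
      density_at(channel, protocol$holding_mv,
                 h_inf(channel, protocol$holding_mv)) +
      cell$leak_conductance_ns *
        (protocol$holding_mv - cell$leak_reversal_mv)
    v <- c(rep(v_pre, n_base), rep(v_step, n_test + 1L))
    cell$capacitance_pf * channel$gmax_density * m_inf(channel, v) *
      (channel$persistent_fraction +
         (1 - channel$persistent_fraction) * h_path) *
      (v - channel$e_rev) +
      cell$leak_conductance_ns * (v - cell$leak_reversal_mv) - i_hold
  }

  h_path_for <- function(v_pre, v_step) {
    tau <- channel$tau_inact_ms
    h_hold <- h_inf(channel, protocol$holding_mv)
    if (protocol$kind == "activation") {
      h_base <- rep(h_hold, n_base)
      h_start <- h_hold
    } else {
      # baseline is the tail of the 250 ms prepulse: h has been relaxing
      # from the holding steady state since the prepulse began
      t0 <- protocol$prepulse_ms - protocol$baseline_ms
      hp <- h_inf(channel, v_pre)
      tb <- t0 + (seq_len(n_base) - 1L) * dt
      h_base <- hp + (h_hold - hp) * exp(-tb / tau)
      h_start <- hp + (h_hold - hp) * exp(-protocol$prepulse_ms / tau)
    }
    hs <- h_inf(channel, v_step)
    tt <- (0:n_test) * dt
    c(h_base, hs + (h_start - hs) * exp(-tt / tau))
  }

  sweep_pair <- function(v_pre, v_step) {
    det(v_pre, v_step, h_path_for(v_pre, v_step))
  }

  n_t <- length(time_ms)
  n_s <- length(steps)
  sweeps <- matrix(NA_real_, n_t, n_s, dimnames = list(NULL, steps))
  p6_sweeps <- if (p6) vector("list", n_s) else NULL

  for (j in seq_len(n_s)) {
    if (protocol$kind == "activation") {
      v_pre <- protocol$holding_mv; v_step <- steps[j]
    } else {
      v_pre <- steps[j]; v_step <- protocol$test_mv
    }
    sweeps[, j] <- sweep_pair(v_pre, v_step) +
      stats::rnorm(n_t, 0, noise$sd_pa)
    if (p6) {
      # 1/6-amplitude command from the subsweep holding, signed by polarity
      scl <- function(v) {
        p6_holding_mv + p6_polarity * (v - protocol$holding_mv) / 6
      }
      base <- sweep_pair(scl(v_pre), scl(v_step))
      p6_sweeps[[j]] <- matrix(base, n_t, 6L) +
        matrix(stats::rnorm(n_t * 6L, 0, noise$sd_pa), n_t, 6L)
    }
  }

  structure(list(
    time_ms = time_ms, sweeps = sweeps, command_mv = steps,
    capacitance_pf = cell$capacitance_pf,
    depol_onset_ms = onset, protocol = protocol,
    p6_sweeps = p6_sweeps, p6_scale = p6_polarity / 6,
    meta = list(ph_e = ph_e, cell_id = cell_id, seed = noise$seed,
                sd_pa = noise$sd_pa),
    corrections = character(0)
  ), class = "vc_recording")
}

#' @export
print.vc_recording <- function(x, ...) {
  cat(sprintf("Whole-cell %s recording: %d sweeps x %d samples (%g kHz)\n",
              x$protocol$kind, ncol(x$sweeps), nrow(x$sweeps),
              x$protocol$sample_khz))
  cat(sprintf("  capacitance %.1f pF; depolarisation at %g ms; pH_e %s\n",
              x$capacitance_pf, x$depol_onset_ms,
              format(x$meta$ph_e)))
  if (length(x$corrections)) {
    cat("  corrections applied:", paste(x$corrections, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.vc_recording <- function(x, steps = NULL, ...) {
  j <- if (is.null(steps)) seq_len(ncol(x$sweeps)) else
    match(steps, x$command_mv)
  graphics::matplot(x$time_ms, x$sweeps[, j, drop = FALSE], type = "l",
                    lty = 1, xlab = "Time (ms)", ylab = "Current (pA)", ...)
  graphics::abline(v = x$depol_onset_ms, lty = 3)
  invisible(x)
}

#' Write / read a recording as CSV plus JSON sidecar
#'
#' The CSV holds time in ms in the first column and one column per command
#' step, with a header row of command voltages.  The sidecar carries
#' capacitance, pH, protocol and seed so a recording round-trips losslessly
#' (P/6 subsweeps are not serialised).
#'
#' @param recording A `vc_recording`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_recording()`: the path, invisibly.  `read_recording()`:
#'   a `vc_recording` (without P/6 subsweeps).
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "vc_recording"))
  df <- data.frame(time_ms = recording$time_ms, recording$sweeps,
                   check.names = FALSE)
  names(df) <- c("time_ms", as.character(recording$command_mv))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(
    capacitance_pf = recording$capacitance_pf,
    ph_e = recording$meta$ph_e,
    cell_id = recording$meta$cell_id,
    seed = recording$meta$seed,
    depol_onset_ms = recording$depol_onset_ms,
    corrections = recording$corrections,
    protocol = unclass(recording$protocol)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  proto <- side$protocol
  protocol <- structure(lapply(proto, function(v) {
    if (is.null(v)) NA_real_ else v
  }), class = "vc_protocol")
  sweeps <- as.matrix(df[, -1L, drop = FALSE])
  structure(list(
    time_ms = df$time_ms, sweeps = sweeps,
    command_mv = as.numeric(colnames(sweeps)),
    capacitance_pf = side$capacitance_pf,
    depol_onset_ms = side$depol_onset_ms,
    protocol = protocol,
    p6_sweeps = NULL,
    meta = list(ph_e = side$ph_e, cell_id = side$cell_id, seed = side$seed,
                sd_pa = NA_real_),
    corrections = as.character(side$corrections %||% character(0))
  ), class = "vc_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
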