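# shared fixtures, built in code; memoised because recordings are reused
.fixtures <- new.env(parent = emptyenv())

noiseless_recording <- function(ph_e = 7.2, kind = "activation") {
  key <- paste(ph_e, kind, sep = "_")
  if (is.null(.fixtures[[key]])) {
    proto <- if (kind == "activation") {
      make_activation_protocol(10)
    } else {
      make_inactivation_protocol(10)
    }
    .fixtures[[key]] <- simulate_recording(
      nav15_channel(ph_e), cell_model(), proto,
      noise_model(sd_pa = 0, seed = 1), ph_e = ph_e)
  }
  .fixtures[[key]]
}

corrected <- function(recording) {
  noise_correct(leak_subtract(recording))
}

# hand-built recording object with known sweep content, for estimator
# contract tests that should not depend on the generator
flat_recording <- function(level_pa = -10, capacitance_pf = 20,
                           n_ms = 60, khz = 10, onset_ms = 10) {
  t <- seq(0, n_ms, by = 1 / khz)
  structure(list(
    time_ms = t,
    sweeps = matrix(ifelse(t >= onset_ms, level_pa, 0), ncol = 1,
                    dimnames = list(NULL, "0")),
    command_mv = 0,
    capacitance_pf = capacitance_pf,
    depol_onset_ms = onset_ms,
    protocol = make_activation_protocol(10, sample_khz = khz),
    p6_sweeps = NULL, p6_scale = -1 / 6,
    meta = list(ph_e = NA, cell_id = NA, seed = NA, sd_pa = 0),
    corrections = character(0)
  ), class = "vc_recording")
}
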