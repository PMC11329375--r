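#' Whole-cell voltage-clamp protocol specifications
#'
#' Constructors for the two standard gating protocols used to characterise
#' voltage-gated Na+ channels in carcinoma cells.
#'
#' `make_activation_protocol()`: the cell is held at -120 mV for 250 ms and
#' then depolarised to test potentials in 5 or 10 mV steps between -120 mV
#' and +30 mV for 50 ms.  The first step equals the holding level and is a
#' null sweep.
#'
#' `make_inactivation_protocol()`: after holding at -120 mV for 250 ms, a
#' 250 ms conditioning prepulse is applied in 5 or 10 mV steps between
#' -120 mV and +30 mV, followed by a 50 ms test pulse to -10 mV.  The
#' -120 mV prepulse gives full availability and anchors the normalization.
#'
#' @param increment_mv Command-step increment, 5 or 10 mV.
#' @param sample_khz Sampling rate, kHz.
#' @param baseline_ms Pre-depolarisation baseline retained in each emitted
#'   trace, ms (used for noise estimation).
#' @return An object of class `vc_protocol`: a list with fields
#'   `kind`, `holding_mv`, `holding_ms`, `step_min_mv`, `step_max_mv`,
#'   `step_increment_mv`, `prepulse_ms` (inactivation only), `test_mv`
#'   (inactivation only), `test_ms`, `sample_khz`, `baseline_ms`.
#' @examples
#' p <- make_activation_protocol(10)
#' protocol_steps(p)  # 16 command levels, -120 .. +30 mV
#' @export
make_activation_protocol <- function(increment_mv = 10, sample_khz = 50,
                                     baseline_ms = 10) {
  check_increment(increment_mv)
  stop_if_not_positive(sample_khz, "sample_khz")
  stop_if_not_positive(baseline_ms, "baseline_ms")
  structure(list(
    kind = "activation",
    holding_mv = -120, holding_ms = 250,
    step_min_mv = -120, step_max_mv = 30,
    step_increment_mv = increment_mv,
    prepulse_ms = NA_real_, test_mv = NA_real_,
    test_ms = 50,
    sample_khz = sample_khz, baseline_ms = baseline_ms
  ), class = "vc_protocol")
}

#' @rdname make_activation_protocol
#' @export
make_inactivation_protocol <- function(increment_mv = 10, sample_khz = 50,
                                       baseline_ms = 10) {
  check_increment(increment_mv)
  stop_if_not_positive(sample_khz, "sample_khz")
  stop_if_not_positive(baseline_ms, "baseline_ms")
  structure(list(
    kind = "inactivation",
    holding_mv = -120, holding_ms = 250,
    step_min_mv = -120, step_max_mv = 30,
    step_increment_mv = increment_mv,
    prepulse_ms = 250, test_mv = -10,
    test_ms = 50,
    sample_khz = sample_khz, baseline_ms = baseline_ms
  ), class = "vc_protocol")
}

check_increment <- function(increment_mv) {
  if (!is.numeric(increment_mv) || length(increment_mv) != 1L ||
      !(increment_mv %in% c(5, 10))) {
    stop("`increment_mv` must be 5 or 10 (protocol specification)",
         call. = FALSE)
  }
  invisible(increment_mv)
}

#' Command (or prepulse) voltage levels of a protocol
#'
#' @param protocol A `vc_protocol`.
#' @return Numeric vector of step levels, mV.
#' @export
protocol_steps <- function(protocol) {
  stopifnot(inherits(protocol, "vc_protocol"))
  seq(protocol$step_min_mv, protocol$step_max_mv,
      by = protocol$step_increment_mv)
}

#' @export
print.vc_protocol <- function(x, ...) {
  cat(sprintf("Voltage-clamp %s protocol\n", x$kind))
  cat(sprintf("  holding %g mV / %g ms; steps %g..%g mV by %g mV\n",
              x$holding_mv, x$holding_ms,
              x$step_min_mv, x$step_max_mv, x$step_increment_mv))
  if (x$kind == "inactivation") {
    cat(sprintf("  prepulse %g ms, test pulse %g mV / %g ms\n",
                x$prepulse_ms, x$test_mv, x$test_ms))
  } else {
    cat(sprintf("  test duration %g ms\n", x$test_ms))
  }
  cat(sprintf("  sampling %g kHz, %g ms baseline per trace\n",
              x$sample_khz, x$baseline_ms))
  invisible(x)
}
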