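#' Parameters of the acidification-current positive feedback loop
#'
#' The loop couples extracellular pH to persistent Na+ current (more
#' acidic pH_e increases the persistent current), the current to
#' glycolytic H+ export through the stoichiometric chain of
#' [predict_ecar()], and the H+ export back to pH_e against a first-order
#' relaxation toward the bath/perfusion pH:
#' `dpH_e/dt = relaxation * (ph_bath - pH_e) - gain * ECAR(pH_e) / 1000`
#' (per-minute units; ECAR in mpH/min).
#'
#' The default current-pH map is linear between the two measured anchors
#' (-0.31 pA/pF at pH 7.2 and -0.71 pA/pF at pH 6.2), clamped flat
#' outside `[6.0, 7.4]`; only two pH points were measured, so the
#' interpolation form is a declared assumption and a log-[H+]-linear
#' alternative is provided.
#'
#' @param ph_bath Bulk/perfusion pH.
#' @param relaxation_per_min First-order pH_e relaxation rate toward
#'   `ph_bath`, 1/min (> 0).
#' @param gain Dimensionless multiplier on the acid source; 0 disables
#'   the feedback.
#' @param map `"linear"` (pH-linear) or `"log_h"` (linear in [H+]).
#' @param anchors 2x2 matrix-like: pH values and anchored persistent
#'   densities, pA/pF.
#' @param clamp pH range outside which the map is held flat.
#' @param capacitance_pf Capacitance used in the flux conversion, pF.
#' @param stoich,well Stoichiometry and well geometry for the acid
#'   source.
#' @return Object of class `feedback_params`.
#' @export
feedback_params <- function(ph_bath = 7.4, relaxation_per_min = 0.01,
                            gain = 1, map = c("linear", "log_h"),
                            anchors = cbind(ph = c(7.2, 6.2),
                                            density = c(-0.31, -0.71)),
                            clamp = c(6.0, 7.4),
                            capacitance_pf = 20,
                            stoich = stoichiometry_params(),
                            well = well_geometry()) {
  map <- match.arg(map)
  stop_if_not_positive(relaxation_per_min, "relaxation_per_min")
  stop_if_negative(gain, "gain")
  stop_if_not_scalar(ph_bath, "ph_bath")
  anchors <- as.matrix(anchors)
  if (nrow(anchors) != 2L) stop("`anchors` needs exactly two pH points",
                                call. = FALSE)
  structure(list(ph_bath = ph_bath,
                 relaxation_per_min = relaxation_per_min,
                 gain = gain, map = map, anchors = anchors,
                 clamp = clamp, capacitance_pf = capacitance_pf,
                 stoich = stoich, well = well),
            class = "feedback_params")
}

#' Persistent current density as a function of extracellular pH
#'
#' Monotone non-increasing map anchored at the two measured conditions;
#' see [feedback_params()] for the interpolation forms.
#'
#' @param params A `feedback_params`.
#' @param ph_e Extracellular pH value(s).
#' @return Persistent current density, pA/pF (negative).
#' @export
current_vs_ph <- function(params, ph_e) {
  stopifnot(inherits(params, "feedback_params"))
  ph <- pmin(pmax(unname(ph_e), params$clamp[1]), params$clamp[2])
  a <- unname(params$anchors)
  p1 <- a[1, 1]; d1 <- a[1, 2]
  p2 <- a[2, 1]; d2 <- a[2, 2]
  if (params$map == "linear") {
    d1 + (ph - p1) * (d2 - d1) / (p2 - p1)
  } else {
    h <- 10^(-ph); h1 <- 10^(-p1); h2 <- 10^(-p2)
    d1 + (h - h1) * (d2 - d1) / (h2 - h1)
  }
}

# instantaneous acid source, mpH/min, at a given pH_e
acid_source <- function(params, ph_e) {
  dens <- current_vs_ph(params, ph_e)
  vapply(dens, function(d) {
    predict_ecar(d, params$capacitance_pf, params$stoich,
                 params$well)$ecar_mpH_min
  }, numeric(1))
}

#' Steady state of the feedback loop
#'
#' Solves the scalar fixed-point equation
#' `pH* = ph_bath - gain * ECAR(pH*) / (1000 * relaxation)` by damped
#' fixed-point iteration with a bisection fallback, to `|dpH| < 1e-9`.
#' The loop map's contraction modulus is estimated numerically; a
#' non-contractive map falls straight through to bisection.
#'
#' @param params A [feedback_params()].
#' @param tol Convergence tolerance on pH.
#' @param max_iter Iteration cap before the bisection fallback.
#' @return Object of class `feedback_state`: list with `ph_e`,
#'   `persistent_density`, `acid_source_mpH_min`, `converged`,
#'   `iterations`, `method`.
#' @export
feedback_steady_state <- function(params, tol = 1e-9, max_iter = 200) {
  stopifnot(inherits(params, "feedback_params"))
  g <- function(p) {
    params$ph_bath - params$gain * acid_source(params, p) /
      (1000 * params$relaxation_per_min)
  }
  guard <- c(5.5, 8.0)
  p <- params$ph_bath
  lambda <- 0.5
  method <- "damped_fixed_point"
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p_new <- (1 - lambda) * p + lambda * g(p)
    p_new <- min(max(p_new, guard[1]), guard[2])
    if (abs(p_new - p) < tol * lambda) {
      p <- p_new; converged <- TRUE; break
    }
    p <- p_new
  }
  if (!converged) {
    # bisection on f(p) = g(p) - p; g is non-increasing in p's acid load,
    # so f is monotone enough to bracket on the guard interval
    method <- "bisection"
    lo <- guard[1]; hi <- max(params$ph_bath, guard[1] + 0.1)
    flo <- g(lo) - lo; fhi <- g(hi) - hi
    if (flo * fhi > 0) {
      stop(sprintf(
        "steady state not bracketed on [%.2f, %.2f]: f = %.3g, %.3g",
        lo, hi, flo, fhi), call. = FALSE)
    }
    for (it in seq_len(200)) {
      p <- (lo + hi) / 2
      f <- g(p) - p
      if (abs(f) < tol || (hi - lo) / 2 < tol) { converged <- TRUE; break }
      if (flo * f < 0) { hi <- p; fhi <- f } else { lo <- p; flo <- f }
    }
  }
  structure(list(
    ph_e = p,
    persistent_density = current_vs_ph(params, p),
    acid_source_mpH_min = acid_source(params, p),
    converged = converged, iterations = it, method = method
  ), class = "feedback_state")
}

#' @export
print.feedback_state <- function(x, ...) {
  cat(sprintf(
    "Feedback steady state: pH_e %.4f (persistent %.3f pA/pF, %.3f mpH/min)\n",
    x$ph_e, x$persistent_density, x$acid_source_mpH_min))
  cat(sprintf("  %s, %d iterations, converged: %s\n",
              x$method, x$iterations, x$converged))
  invisible(x)
}

#' Integrate the feedback loop dynamics
#'
#' Fixed-step fourth-order Runge-Kutta integration (via
#' `deSolve::ode(method = "rk4")`) of the scalar pH_e equation; the
#' terminal state agrees with [feedback_steady_state()] for a
#' sufficiently long span.  A guard range aborts on step-size
#' instability.
#'
#' @param params A [feedback_params()].
#' @param ph0 Initial extracellular pH.
#' @param t_span Total simulated time, minutes.
#' @param dt Time step, minutes (> 0).
#' @return Object of class `feedback_trajectory`: data.frame with
#'   `time_min`, `ph_e`, `persistent_density`, `acid_source_mpH_min`.
#' @export
feedback_dynamics <- function(params, ph0 = NULL, t_span = 1500, dt = 0.5) {
  stopifnot(inherits(params, "feedback_params"))
  stop_if_not_positive(dt, "dt")
  if (is.null(ph0)) ph0 <- params$ph_bath
  guard <- c(5.5, 8.0)
  rhs <- function(t, y, parms) {
    list(params$relaxation_per_min * (params$ph_bath - y[1]) -
           params$gain * acid_source(params, y[1]) / 1000)
  }
  times <- seq(0, t_span, by = dt)
  sol <- deSolve::ode(y = c(ph = ph0), times = times, func = rhs,
                      parms = NULL, method = "rk4")
  ph <- sol[, "ph"]
  if (any(!is.finite(ph)) || any(ph < guard[1]) || any(ph > guard[2])) {
    stop("pH guard breached: reduce `dt` (step-size instability)",
         call. = FALSE)
  }
  out <- data.frame(time_min = sol[, "time"], ph_e = ph,
                    persistent_density = current_vs_ph(params, ph),
                    acid_source_mpH_min = acid_source(params, ph))
  class(out) <- c("feedback_trajectory", "data.frame")
  out
}

#' @export
plot.feedback_trajectory <- function(x, ...) {
  plot(x$time_min, x$ph_e, type = "l", xlab = "Time (min)",
       ylab = expression(pH[e]), ...)
  invisible(x)
}

#' Closed-loop vs open-loop acidification ratio
#'
#' Ratio `(ph_bath - pH*_closed) / (ph_bath - pH*_open)`, where the
#' open-loop steady state fixes the persistent current at its bath-pH
#' value.  The ratio is >= 1 whenever the current-pH map is monotone
#' non-increasing: the loop amplifies its own acid source.
#'
#' @param params A [feedback_params()] with `gain > 0`.
#' @return List with `amplification`, `ph_closed`, `ph_open`.
#' @export
feedback_amplification <- function(params) {
  stopifnot(inherits(params, "feedback_params"))
  if (params$gain <= 0) stop("`gain` must be > 0", call. = FALSE)
  closed <- feedback_steady_state(params)
  open_drop <- params$gain * acid_source(params, params$ph_bath) /
    (1000 * params$relaxation_per_min)
  if (open_drop <= 0) {
    stop("open-loop acidification is zero: amplification undefined",
         call. = FALSE)
  }
  ph_open <- params$ph_bath - open_drop
  list(amplification = (params$ph_bath - closed$ph_e) / open_drop,
       ph_closed = closed$ph_e, ph_open = ph_open)
}
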