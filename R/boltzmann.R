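#' Boltzmann gating curve
#'
#' The two-state Boltzmann function used throughout voltage-clamp analysis,
#' `y = 1 / (1 + exp((v_half - v) / k))`.  A single signed-slope form covers
#' both gating processes: activation curves rise with depolarisation
#' (`k > 0`) while steady-state inactivation (availability) curves fall
#' (`k < 0`).
#'
#' @param v Membrane potential(s), mV.
#' @param v_half Half-(in)activation voltage, mV.
#' @param k Slope factor, mV; sign selects the direction of the curve.
#' @return Numeric vector of gating values in (0, 1).
#' @examples
#' boltzmann(-15.2, v_half = -15.2, k = 10.7)  # 0.5 at the midpoint
#' @export
boltzmann <- function(v, v_half, k) {
  stop_if_not_scalar(v_half, "v_half")
  stop_if_not_scalar(k, "k")
  if (k == 0) stop("`k` must be nonzero", call. = FALSE)
  1 / (1 + exp((v_half - v) / k))
}

#' Fit a Boltzmann curve to a gating data set
#'
#' Least-squares fit of `y = 1 / (1 + exp((v_half - v) / k))` to a normalized
#' activation (conductance-voltage) or steady-state inactivation
#' (availability-voltage) curve, via bounded Levenberg-Marquardt.
#'
#' The signed-slope single form means one fitter serves both curve kinds:
#' `kind = "activation"` constrains `k` to `[1, 50]` mV and
#' `kind = "inactivation"` to `[-50, -1]` mV.  Starting values follow the
#' usual heuristics: `v_half` from linear interpolation of the 0.5 crossing,
#' `k` from a quarter of the 0.25-0.75 crossing span (signed by kind).
#'
#' @param voltage Command or prepulse voltages, mV (>= 4 points spanning the
#'   transition).
#' @param response Normalized response in (approximately) `[0, 1]`.
#' @param kind `"activation"` or `"inactivation"`.
#' @param free_amplitude Also fit a scale factor `A` (as in a free-Gmax
#'   conductance fit), `y = A / (1 + exp((v_half - v) / k))`.  Useful when
#'   the normalization reference does not saturate the curve - a
#'   max-normalized activation curve whose most depolarised step still
#'   sits below saturation is otherwise inflated by `1/y(v_max)`.
#' @return An object of class `boltzmann_fit` with components `v_half_mv`,
#'   `k_mv`, `kind`, `rss`, `converged`, plus the data used.  Methods:
#'   [print.boltzmann_fit()], [coef.boltzmann_fit()],
#'   [predict.boltzmann_fit()], [residuals.boltzmann_fit()],
#'   [plot.boltzmann_fit()].
#' @examples
#' v <- seq(-120, 30, by = 10)
#' fit <- fit_boltzmann(v, boltzmann(v, -15.2, 10.7), "activation")
#' coef(fit)
#' @export
fit_boltzmann <- function(voltage, response,
                          kind = c("activation", "inactivation"),
                          free_amplitude = FALSE) {
  kind <- match.arg(kind)
  if (!is.numeric(voltage) || !is.numeric(response) ||
      length(voltage) != length(response)) {
    stop("`voltage` and `response` must be numeric vectors of equal length",
         call. = FALSE)
  }
  ok <- is.finite(voltage) & is.finite(response)
  voltage <- voltage[ok]; response <- response[ok]
  if (length(voltage) < 4L) {
    stop("need at least 4 finite points spanning the transition",
         call. = FALSE)
  }

  sgn <- if (kind == "activation") 1 else -1
  start <- boltzmann_start(voltage, response, sgn)
  dat <- data.frame(v = voltage, y = response)
  fit <- tryCatch(
    if (free_amplitude) {
      minpack.lm::nlsLM(
        y ~ amp / (1 + exp((v_half - v) / k)),
        data = dat,
        start = list(v_half = start$v_half, k = start$k, amp = 1),
        lower = c(v_half = -200, k = if (sgn > 0) 1 else -50, amp = 0.5),
        upper = c(v_half = 100, k = if (sgn > 0) 50 else -1, amp = 1.5),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      minpack.lm::nlsLM(
        y ~ 1 / (1 + exp((v_half - v) / k)),
        data = dat,
        start = list(v_half = start$v_half, k = start$k),
        lower = c(v_half = -200, k = if (sgn > 0) 1 else -50),
        upper = c(v_half = 100, k = if (sgn > 0) 50 else -1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    },
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    out <- list(v_half_mv = NA_real_, k_mv = NA_real_, kind = kind,
                rss = NA_real_, converged = FALSE,
                message = conditionMessage(fit),
                voltage = voltage, response = response)
    class(out) <- "boltzmann_fit"
    warning("Boltzmann fit did not converge: ", out$message, call. = FALSE)
    return(out)
  }

  cf <- stats::coef(fit)
  out <- list(
    v_half_mv = unname(cf["v_half"]),
    k_mv      = unname(cf["k"]),
    amplitude = if (free_amplitude) unname(cf["amp"]) else 1,
    kind      = kind,
    rss       = sum(stats::residuals(fit)^2),
    converged = isTRUE(fit$convInfo$isConv),
    message   = fit$convInfo$stopMessage,
    voltage   = voltage,
    response  = response
  )
  class(out) <- "boltzmann_fit"
  out
}

# midpoint/slope starting values; sgn = +1 activation, -1 inactivation
boltzmann_start <- function(voltage, response, sgn) {
  o <- order(voltage)
  v <- voltage[o]; y <- response[o]
  cross <- function(level) {
    # first crossing of `level` in the direction of the curve
    yy <- if (sgn > 0) y else rev(y)
    vv <- if (sgn > 0) v else rev(v)
    i <- which(yy[-length(yy)] <= level & yy[-1] > level)
    if (length(i) == 0L) return(NA_real_)
    i <- i[1L]
    vv[i] + (level - yy[i]) * (vv[i + 1L] - vv[i]) / (yy[i + 1L] - yy[i])
  }
  v50 <- cross(0.5)
  if (!is.finite(v50)) v50 <- stats::median(v)
  v25 <- cross(0.25); v75 <- cross(0.75)
  k0 <- if (is.finite(v25) && is.finite(v75)) abs(v75 - v25) / 4 else 8
  k0 <- min(max(k0, 1), 50)
  list(v_half = v50, k = sgn * k0)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann %s fit\n", x$kind))
  cat(sprintf("  v_half = %.2f mV, k = %.2f mV\n", x$v_half_mv, x$k_mv))
  cat(sprintf("  rss = %.3g over %d points; converged: %s\n",
              x$rss, length(x$voltage), x$converged))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(v_half_mv = object$v_half_mv, k_mv = object$k_mv)
}

#' Evaluate a fitted Boltzmann curve
#'
#' @param object A [fit_boltzmann()] result.
#' @param newdata Optional voltages (mV); defaults to the fitted voltages.
#' @param type `"gating"` returns the unit-amplitude gating curve (what
#'   availability and window-current calculations need); `"response"`
#'   includes the fitted amplitude.
#' @param ... Unused.
#' @export
predict.boltzmann_fit <- function(object, newdata = NULL,
                                  type = c("gating", "response"), ...) {
  type <- match.arg(type)
  v <- if (is.null(newdata)) object$voltage else newdata
  if (is.list(v)) v <- v[[1L]]
  amp <- if (type == "response") object$amplitude %||% 1 else 1
  amp * boltzmann(v, object$v_half_mv, object$k_mv)
}

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  object$response - predict(object, type = "response")
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  vgrid <- seq(min(x$voltage), max(x$voltage), length.out = 200)
  plot(x$voltage, x$response, xlab = "Voltage (mV)",
       ylab = if (x$kind == "activation") "G/Gmax" else "I/Imax",
       main = sprintf("Boltzmann %s fit", x$kind), ...)
  graphics::lines(vgrid, boltzmann(vgrid, x$v_half_mv, x$k_mv))
  graphics::abline(v = x$v_half_mv, lty = 3)
  invisible(x)
}
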