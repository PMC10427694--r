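#' Minimum-jerk trajectory parameters
#'
#' Defines a one-dimensional point-to-point reference movement: the quintic
#' minimum-jerk trajectory (MJT) from a start position `x0` to a target
#' position `xf` over a movement duration `d`, beginning at time `t_s`.
#' Positions are expressed in percent of workspace (screen) width, times in
#' seconds. `x0 == xf` is permitted and yields a constant trajectory.
#'
#' @param x0 Start position (% workspace width).
#' @param xf Target position (% workspace width).
#' @param d Movement duration in seconds (must be > 0).
#' @param t_s Start time in seconds (default 0; traces are conventionally
#'   re-based so that movement onset is time zero).
#' @return An object of class `mjt_params`.
#' @examples
#' p <- mjt_params(x0 = 0, xf = 50, d = 1)
#' mjt_position(p, 0.5)
#' @export
mjt_params <- function(x0, xf, d, t_s = 0) {
  stopifnot(is.numeric(x0), is.numeric(xf), is.numeric(d), is.numeric(t_s),
            length(x0) == 1L, length(xf) == 1L, length(d) == 1L,
            length(t_s) == 1L, is.finite(x0), is.finite(xf), is.finite(t_s))
  if (!is.finite(d) || d <= 0) {
    stop("movement duration 'd' must be a positive, finite number of seconds")
  }
  structure(list(x0 = x0, xf = xf, d = d, t_s = t_s, t_f = t_s + d),
            class = "mjt_params")
}

#' @export
print.mjt_params <- function(x, ...) {
  cat(sprintf(
    "Minimum-jerk trajectory: %.4g%% -> %.4g%% over %.4g s (t_s = %.4g s)\n",
    x$x0, x$xf, x$d, x$t_s))
  invisible(x)
}

# Normalised time tau in [0, 1]; errors outside unless clamp = TRUE.
mjt_tau <- function(params, t, clamp = FALSE) {
  tau <- (t - params$t_s) / params$d
  if (clamp) {
    tau <- pmin(pmax(tau, 0), 1)
  } else if (any(tau < -1e-12 | tau > 1 + 1e-12)) {
    stop(sprintf("time outside the movement interval [%.6g, %.6g]; ",
                 params$t_s, params$t_f),
         "use clamp = TRUE only if extrapolation-by-saturation is intended")
  }
  pmin(pmax(tau, 0), 1)
}

#' Minimum-jerk position
#'
#' Closed-form position of the minimum-jerk trajectory,
#' \eqn{x(t) = x_0 + (x_f - x_0)(10\tau^3 - 15\tau^4 + 6\tau^5)} with
#' \eqn{\tau = (t - t_s)/d}. Times outside \eqn{[t_s, t_f]} raise an error
#' unless `clamp = TRUE`, in which case the trajectory saturates at its
#' endpoints (intended for plotting a reference over a longer trial window).
#'
#' @param params An [mjt_params()] object.
#' @param t Numeric vector of times (s).
#' @param clamp Saturate rather than error outside the movement interval.
#' @return Positions (% workspace width), same length as `t`.
#' @export
mjt_position <- function(params, t, clamp = FALSE) {
  stopifnot(inherits(params, "mjt_params"))
  tau <- mjt_tau(params, t, clamp)
  params$x0 + (params$xf - params$x0) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' Minimum-jerk velocity
#'
#' Closed-form velocity of the minimum-jerk trajectory,
#' \eqn{v(t) = (x_f - x_0)(30\tau^2 - 60\tau^3 + 30\tau^4)/d}. The profile is
#' the classic single-peaked bell, symmetric about the movement midpoint,
#' with peak value \eqn{1.875\,(x_f - x_0)/d} at \eqn{\tau = 1/2}.
#'
#' @inheritParams mjt_position
#' @return Velocities (% workspace width per second), same length as `t`.
#' @export
mjt_velocity <- function(params, t, clamp = FALSE) {
  stopifnot(inherits(params, "mjt_params"))
  tau <- mjt_tau(params, t, clamp)
  (params$xf - params$x0) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / params$d
}

#' Peak velocity of a minimum-jerk movement
#'
#' The analytic maximum `1.875 * (xf - x0) / d`, attained at the movement
#' midpoint.
#'
#' @inheritParams mjt_position
#' @return A scalar velocity (%/s); negative for negative-going movements.
#' @export
mjt_peak_velocity <- function(params) {
  stopifnot(inherits(params, "mjt_params"))
  1.875 * (params$xf - params$x0) / params$d
}

#' Integrated squared-jerk cost
#'
#' The cost functional the minimum-jerk model minimises:
#' \eqn{\int_{t_s}^{t_f} \dddot{x}(t)^2\, dt}. For `mjt_params` the third
#' derivative of the quintic is evaluated analytically and integrated by
#' composite trapezoid on a dense grid (the closed form is
#' \eqn{720 (x_f-x_0)^2 / d^5}); for a sampled trace the third derivative is
#' estimated by repeated finite differencing of the positions and integrated
#' the same way.
#'
#' @param x An [mjt_params()] object or a `reference_trace` /
#'   list with `times` and `positions` (at least 4 samples).
#' @param n_grid Grid size for the analytic quadrature.
#' @return Scalar jerk cost (%^2 / s^5).
#' @export
mjt_jerk_cost <- function(x, n_grid = 2001L) {
  if (inherits(x, "mjt_params")) {
    # x'''(t) = (xf - x0) * (60 - 360 tau + 360 tau^2) / d^3
    tau <- seq(0, 1, length.out = n_grid)
    jerk <- (x$xf - x$x0) * (60 - 360 * tau + 360 * tau^2) / x$d^3
    return(trapz(tau * x$d + x$t_s, jerk^2))
  }
  times <- x$times
  pos <- x$positions
  if (is.null(times) || is.null(pos) || length(pos) < 4L) {
    stop("sampled jerk cost needs a trace with at least 4 samples")
  }
  n <- length(pos)
  h <- mean(diff(times))
  # third difference x[i+3] - 3 x[i+2] + 3 x[i+1] - x[i], centred between
  # samples; squared-jerk quadrature over the centres plus constant-jerk
  # extension to the interval ends (the tails carry the largest jerk)
  j <- (pos[4:n] - 3 * pos[3:(n - 1)] + 3 * pos[2:(n - 2)] -
          pos[1:(n - 3)]) / h^3
  centers <- times[1:(n - 3)] + 1.5 * h
  trapz(centers, j^2) +
    j[1]^2 * (centers[1] - times[1]) +
    j[length(j)]^2 * (times[n] - centers[length(centers)])
}

# Composite trapezoid rule.
trapz <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Sample a minimum-jerk reference trace
#'
#' Discretises the closed-form trajectory on a uniform grid from `t_s` to
#' `t_f` inclusive, at sampling rate `fs` (Hz). A duration `d` sampled at
#' `fs` yields `floor(d * fs) + 1` points (61 at the task's 60 Hz for a 1 s
#' movement).
#'
#' @param params An [mjt_params()] object.
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `reference_trace`: list with `times`,
#'   `positions`, `velocities` and the generating `params`.
#' @export
sample_mjt <- function(params, fs = 60) {
  stopifnot(inherits(params, "mjt_params"))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("sampling rate 'fs' must be a positive number of Hz")
  }
  n <- floor(params$d * fs)
  times <- params$t_s + seq(0, n) / fs
  # guarantee the final endpoint is represented even when d*fs is not integral
  if (times[length(times)] < params$t_f - 1e-12) {
    times <- c(times, params$t_f)
  }
  structure(
    list(times = times,
         positions = mjt_position(params, times),
         velocities = mjt_velocity(params, times),
         params = params),
    class = "reference_trace")
}

#' @export
print.reference_trace <- function(x, ...) {
  cat(sprintf("Sampled minimum-jerk reference: %d samples over [%.4g, %.4g] s\n",
              length(x$times), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Normalised time at which the trajectory crosses a completion fraction
#'
#' Solves \eqn{10\tau^3 - 15\tau^4 + 6\tau^5 = r} for \eqn{\tau \in [0, 1]}.
#' Used to relate the full minimum-jerk movement duration to the measured
#' time to target under the task's end rule (first crossing of 95% of the
#' target position): for a movement that lands exactly on the target centre,
#' the end rule fires at `mjt_crossing_fraction(0.95)` of the duration
#' (about 0.81).
#'
#' @param r Completion fraction(s) in \[0, 1\].
#' @return Normalised crossing time(s) \eqn{\tau} in \[0, 1\].
#' @export
mjt_crossing_fraction <- function(r) {
  stopifnot(is.numeric(r), all(is.finite(r)), all(r >= 0), all(r <= 1))
  vapply(r, function(ri) {
    if (ri <= 0) return(0)
    if (ri >= 1) return(1)
    stats::uniroot(function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5 - ri,
                   c(0, 1), tol = 1e-12)$root
  }, numeric(1))
}
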