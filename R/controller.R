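#' Turbidostat controller configuration
#'
#' Parameters of the per-well feedback controller. Each service cycle the
#' controller receives one OD measurement and emits one media-replacement
#' command; the command is the fraction of the working volume to exchange,
#' clamped to `[0, y_max]`.
#'
#' @param x_set OD600 setpoint (> 0).
#' @param y_max Maximum replacement fraction per cycle (> 0); the physical
#'   limit of how much volume the robot can move in one service visit.
#' @param dt_hours Nominal cycle interval in hours (> 0).
#' @param alpha First-order filter retention coefficient in `[0, 1]`: the
#'   filtered growth-constant estimate is
#'   `alpha * previous + (1 - alpha) * observed`. Higher values damp
#'   measurement noise harder but track changes in growth rate more slowly.
#' @param k_init Initial growth-constant estimate (1/hour, >= 0) used on the
#'   first call, before any consecutive-measurement estimate exists. The
#'   default 0 means no dilution is issued until growth has been observed,
#'   which protects slow growers from washout at cold start.
#' @return An object of class `controller_config` (a named list).
#' @examples
#' controller_config(x_set = 0.8, dt_hours = 0.5)
#' @export
controller_config <- function(x_set = 0.8, y_max = 1, dt_hours = 0.5,
                              alpha = 0.7, k_init = 0) {
  if (x_set <= 0) abort("x_set must be > 0")
  if (y_max <= 0) abort("y_max must be > 0")
  if (dt_hours <= 0) abort("dt_hours must be > 0")
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  if (k_init < 0) abort("k_init must be >= 0")
  structure(
    list(x_set = x_set, y_max = y_max, dt_hours = dt_hours,
         alpha = alpha, k_init = k_init),
    class = "controller_config"
  )
}

#' @export
print.controller_config <- function(x, ...) {
  cat("<controller_config> x_set =", x$x_set, " y_max =", x$y_max,
      " dt =", x$dt_hours, "h  alpha =", x$alpha, " k_init =", x$k_init, "\n")
  invisible(x)
}

#' Growth-constant estimate from consecutive measurements
#'
#' Given the previous measurement `x_prev` taken just before a replacement of
#' fraction `y_prev` was executed, and the current measurement `x_curr` taken
#' `dt` hours later, the growth constant over the interval is
#' `ln((x_curr / x_prev) * (y_prev + 1)) / dt`: the dilution is undone, then
#' the exponential growth law is inverted. The raw estimate may be negative
#' (death, or noise); the nonnegativity clamp is applied downstream in
#' [filter_k()], not here.
#'
#' @param x_prev,x_curr Consecutive OD600 measurements (> 0).
#' @param y_prev Replacement fraction executed after `x_prev` (>= 0).
#' @param dt Interval between measurements, hours (> 0).
#' @return Raw growth-constant estimate, 1/hour. Vectorized.
#' @examples
#' estimate_k(0.2, 0.4, 0, 1)    # one observed doubling -> ln(2)
#' estimate_k(0.3, 0.2, 0.5, 1)  # change explained entirely by dilution -> 0
#' @export
estimate_k <- function(x_prev, x_curr, y_prev, dt) {
  if (any(x_prev <= 0) || any(x_curr <= 0)) {
    abort("OD measurements must be > 0 (blank or failed read: skip the update)")
  }
  if (any(y_prev < 0)) abort("y_prev must be >= 0")
  if (any(dt <= 0)) abort("dt must be > 0")
  log((x_curr / x_prev) * (y_prev + 1)) / dt
}

#' First-order linear filter for the growth-constant estimate
#'
#' Exponential smoothing to damp measurement noise:
#' `max(0, alpha * k_est_prev + (1 - alpha) * k_obs)`. Negative raw
#' observations are admitted into the filter but the filtered estimate is
#' clamped at zero, because the output law projects growth forward and
#' assumes a nonnegative growth constant.
#'
#' @param k_est_prev Previous filtered estimate (1/hour).
#' @param k_obs New raw observation from [estimate_k()] (may be negative).
#' @param alpha Retention coefficient in `[0, 1]`.
#' @return Filtered, clamped estimate (>= 0). Vectorized.
#' @examples
#' filter_k(0.4, 0.8, 0.5)
#' @export
filter_k <- function(k_est_prev, k_obs, alpha) {
  if (any(alpha < 0) || any(alpha > 1)) abort("alpha must be in [0, 1]")
  pmax(0, alpha * k_est_prev + (1 - alpha) * k_obs)
}

#' Clamped media-replacement command
#'
#' Projects the measured OD forward one cycle with the current growth
#' estimate and chooses the replacement fraction that would bring it back to
#' the setpoint: `x * exp(k_est * dt) / x_set - 1`, clamped to `[0, y_max]`.
#' Below the setpoint with little projected growth the raw value is negative
#' and the command is 0 (the controller cannot concentrate a culture).
#'
#' @param x Current OD600 measurement (>= 0).
#' @param k_est Filtered growth-constant estimate (1/hour, >= 0).
#' @param cfg A [controller_config()].
#' @return Replacement fraction in `[0, y_max]`. Vectorized over `x`, `k_est`.
#' @examples
#' cfg <- controller_config(x_set = 0.8, y_max = 2, dt_hours = 1)
#' compute_command(0.8, log(2), cfg)  # projected doubling -> y = 1
#' @export
compute_command <- function(x, k_est, cfg) {
  stopifnot(inherits(cfg, "controller_config"))
  if (any(x < 0)) abort("x must be >= 0")
  if (any(k_est < 0)) abort("k_est must be >= 0")
  pmax(0, pmin(cfg$y_max, x * exp(k_est * cfg$dt_hours) / cfg$x_set - 1))
}

#' One controller update: measurement in, command and new state out
#'
#' The per-well controller state is the triple (last OD measurement,
#' filtered growth-constant estimate, last issued command). A normal step
#' composes [estimate_k()] (using the state's last measurement and last
#' command), [filter_k()], and [compute_command()]. The first-ever call has
#' no history: it uses `cfg$k_init` as the estimate and skips estimation.
#' A failed or blank read (`x_meas` missing or <= 0) commands 0 and leaves
#' the estimate and last measurement unchanged, so sterile control wells
#' never trigger dilution.
#'
#' @param state A `controller_state` from a previous call, or `NULL` for the
#'   first-ever call.
#' @param x_meas The new OD600 measurement.
#' @param cfg A [controller_config()].
#' @return A list with elements `command` (the replacement fraction) and
#'   `state` (the new `controller_state`: `x_last`, `k_est`, `y_last`).
#' @examples
#' cfg <- controller_config(x_set = 0.8, dt_hours = 0.5)
#' s0 <- controller_step(NULL, 0.4, cfg)
#' s1 <- controller_step(s0$state, 0.5, cfg)
#' @export
controller_step <- function(state, x_meas, cfg) {
  stopifnot(inherits(cfg, "controller_config"))
  if (!is.null(state) && !inherits(state, "controller_state")) {
    abort("state must be NULL or a controller_state")
  }

  if (is.null(x_meas) || is.na(x_meas) || x_meas <= 0) {
    # degraded read: no estimation, no dilution, state otherwise untouched
    if (is.null(state)) {
      state <- new_controller_state(NA_real_, cfg$k_init, 0)
    } else {
      state$y_last <- 0
    }
    return(list(command = 0, state = state))
  }

  if (is.null(state) || is.na(state$x_last)) {
    k_est <- if (is.null(state)) cfg$k_init else state$k_est
  } else {
    k_obs <- estimate_k(state$x_last, x_meas, state$y_last, cfg$dt_hours)
    k_est <- filter_k(state$k_est, k_obs, cfg$alpha)
  }
  y <- compute_command(x_meas, k_est, cfg)
  list(command = y, state = new_controller_state(x_meas, k_est, y))
}

new_controller_state <- function(x_last, k_est, y_last) {
  structure(list(x_last = x_last, k_est = k_est, y_last = y_last),
            class = "controller_state")
}

#' @export
print.controller_state <- function(x, ...) {
  cat("<controller_state> x_last =", x$x_last, " k_est =", x$k_est,
      " y_last =", x$y_last, "\n")
  invisible(x)
}
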