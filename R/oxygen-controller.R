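#' Initialize the oxygen-delivery controller
#'
#' State of the delivery-side logic: it receives one vitals record per
#' second, drives the display, titrates the oxygen flow toward the target
#' saturation band once per minute, stops immediately on signal loss, and
#' restarts (with flow 0) when no record has arrived for longer than the
#' watchdog timeout.
#'
#' @param step Titration step, L/min (default 0.5).
#' @param max_flow Maximum deliverable flow, L/min (default 15).
#' @param v_max Valve drive voltage at `max_flow`, volts (default 10).
#' @param band Target saturation band, percent (default `c(94, 98)`, the
#'   band recommended for most acutely ill patients).
#' @param adjust_period Minimum spacing of titration commands, seconds
#'   (default 60: flow is modified every minute).
#' @param watchdog_timeout Staleness bound, seconds (default 60): if no
#'   record arrives for longer than this the system is restarted with the
#'   valve closed.
#' @param t0 Session start time, seconds.
#' @return An object of class `controller_state`.
#' @export
controller_state <- function(step = 0.5, max_flow = 15, v_max = 10,
                             band = c(94, 98), adjust_period = 60,
                             watchdog_timeout = 60, t0 = 0) {
  check_range(step, "step", 0, Inf, open_lo = TRUE)
  check_range(max_flow, "max_flow", 0, Inf, open_lo = TRUE)
  check_range(v_max, "v_max", 0, Inf, open_lo = TRUE)
  stopifnot(length(band) == 2, band[1] < band[2])
  check_range(band[1], "band[1]", 0, 100)
  check_range(band[2], "band[2]", 0, 100)
  check_range(adjust_period, "adjust_period", 0, Inf, open_lo = TRUE)
  check_range(watchdog_timeout, "watchdog_timeout", 0, Inf, open_lo = TRUE)
  structure(list(current_flow = 0, last_adjust_t = t0, last_record_t = t0,
                 display = "", stalled = FALSE,
                 step = step, max_flow = max_flow, v_max = v_max,
                 band = band, adjust_period = adjust_period,
                 watchdog_timeout = watchdog_timeout),
            class = "controller_state")
}

#' @export
print.controller_state <- function(x, ...) {
  cat(sprintf(
    "<controller_state> flow %.2f L/min, band [%g, %g]%%, step %g L/min per %g s\n",
    x$current_flow, x$band[1], x$band[2], x$step, x$adjust_period))
  invisible(x)
}

# One-row valve-command data frame.
valve_command <- function(t, flow, state, reason) {
  data.frame(t = t, flow = flow,
             voltage = valve_voltage(flow, state$max_flow, state$v_max),
             reason = reason)
}

#' Fixed-step titration law
#'
#' Called at per-minute boundaries with the stabilized (moving-average)
#' saturation: below the band the flow is raised one step, above the band it
#' is lowered one step, inside the band it is held; always clipped to
#' `[0, max_flow]`. Deterministic and non-increasing in SpO2.
#'
#' @param state A `controller_state`.
#' @param smoothed_spo2 Stabilized SpO2, percent.
#' @return The new flow in L/min.
#' @examples
#' st <- controller_state()
#' st$current_flow <- 2
#' decide_flow(st, 90)  # 2.5
#' @export
decide_flow <- function(state, smoothed_spo2) {
  stopifnot(inherits(state, "controller_state"))
  flow <- state$current_flow
  if (smoothed_spo2 < state$band[1]) {
    min(flow + state$step, state$max_flow)
  } else if (smoothed_spo2 > state$band[2]) {
    max(flow - state$step, 0)
  } else {
    flow
  }
}

#' Valve drive voltage for a commanded flow
#'
#' The proportional solenoid valve opens linearly with its input voltage:
#' volts = `v_max * flow / max_flow`, invertible on `[0, max_flow]`.
#'
#' @param flow Commanded flow, L/min, within `[0, max_flow]`.
#' @param max_flow Maximum flow, L/min (default 15).
#' @param v_max Voltage at maximum flow, volts (default 10).
#' @return Volts.
#' @examples
#' valve_voltage(7.5, max_flow = 15, v_max = 10)  # 5
#' @export
valve_voltage <- function(flow, max_flow = 15, v_max = 10) {
  if (!is.numeric(flow) || any(!is.finite(flow)) ||
      any(flow < 0) || any(flow > max_flow))
    stop(sprintf("flow must lie in [0, %g] L/min", max_flow), call. = FALSE)
  v_max * flow / max_flow
}

#' Handle one received vitals record
#'
#' An invalid record (no PPG signal) displays "Please Insert Your Finger"
#' and closes the valve immediately. A valid record updates the display
#' with SpO2 / heart rate / perfusion index and, if at least
#' `adjust_period` seconds have passed since the last adjustment, titrates
#' the flow (a `hold` command is still logged when the saturation is in
#' band).
#'
#' @param state A `controller_state`.
#' @param record A one-row vitals record (fields `t`, `spo2`, `heart_rate`,
#'   `perfusion_index`, `valid`). Records must arrive in time order.
#' @return A list with the updated `state`, the `display` string, and
#'   `command` (a one-row data frame `t`, `flow`, `voltage`, `reason`, or
#'   `NULL` when no command was issued).
#' @export
handle_record <- function(state, record) {
  stopifnot(inherits(state, "controller_state"))
  t <- record$t
  if (t < state$last_record_t)
    stop(sprintf("protocol error: record at t = %g s arrives after t = %g s",
                 t, state$last_record_t), call. = FALSE)
  state$last_record_t <- t
  state$stalled <- FALSE

  if (!isTRUE(record$valid)) {
    state$current_flow <- 0
    state$display <- "Please Insert Your Finger"
    cmd <- valve_command(t, 0, state, "no_signal_stop")
    return(list(state = state, display = state$display, command = cmd))
  }

  state$display <- sprintf("SpO2 %.1f%%  HR %.0f bpm  PI %.2f%%",
                           record$spo2, record$heart_rate,
                           record$perfusion_index)
  cmd <- NULL
  if (t - state$last_adjust_t >= state$adjust_period) {
    new_flow <- decide_flow(state, record$spo2)
    reason <- if (new_flow > state$current_flow) "titrate_up"
              else if (new_flow < state$current_flow) "titrate_down"
              else "hold"
    state$current_flow <- new_flow
    state$last_adjust_t <- t
    cmd <- valve_command(t, new_flow, state, reason)
  }
  list(state = state, display = state$display, command = cmd)
}

#' Watchdog staleness check
#'
#' If no record has arrived for more than the watchdog timeout the system is
#' considered hung: the valve is closed, the pipeline state is reset, and a
#' `watchdog_stop` command is emitted. Exactly one restart is issued per
#' stall episode (the flag clears when a record arrives again).
#'
#' @param state A `controller_state`.
#' @param now Current time, seconds (monotone).
#' @return A list with the updated `state` and `command` (`NULL` if no
#'   action was needed).
#' @export
watchdog_check <- function(state, now) {
  stopifnot(inherits(state, "controller_state"))
  if (!state$stalled && now - state$last_record_t > state$watchdog_timeout) {
    state$stalled <- TRUE
    state$current_flow <- 0
    state$last_adjust_t <- now
    state$display <- "ALARM: no signal - system restarted"
    cmd <- valve_command(now, 0, state, "watchdog_stop")
    return(list(state = state, command = cmd))
  }
  list(state = state, command = NULL)
}
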