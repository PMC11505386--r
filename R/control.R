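# Two-loop controller: outer velocity-form PI from EGCO2 error to sweep
# command (clamped, anti-windup by construction) and inner PI from flow
# error to blower duty.

#' Fresh outer-loop controller state
#'
#' @param cfg A [controller_config()].
#' @return List with `last_error` (mmHg), `last_command` (L/min, starts at
#'   the clamp floor) and `saturated`.
#' @export
new_controller_state <- function(cfg = controller_config()) {
  list(last_error = 0, last_command = cfg$min_sweep, saturated = FALSE)
}

#' One outer-loop PI update (fixed-EGCO2 mode)
#'
#' Velocity-form update of the sweep command from the EGCO2 error
#' `e = measured - target`:
#' `command = clamp(last + kp * (e - e_last) + ki * T * e, min_sweep, max_sweep)`.
#' A positive error (too much exhaust CO2) increases the sweep. Because the
#' increment is applied to the already-clamped previous command, saturation
#' cannot wind up an integral term.
#'
#' @param egco2_measured Sensed EGCO2, mmHg.
#' @param cfg A [controller_config()] with `mode = "fixed_egco2"`.
#' @param state Controller state from [new_controller_state()] or a previous
#'   update.
#' @return List with `command` (L/min) and the updated `state`.
#' @export
pi_update <- function(egco2_measured, cfg = controller_config(),
                      state = new_controller_state(cfg)) {
  if (cfg$mode != "fixed_egco2")
    stop("pi_update applies only in fixed_egco2 mode")
  e <- egco2_measured - cfg$target_egco2
  raw <- state$last_command + cfg$kp * (e - state$last_error) +
    cfg$ki * cfg$update_period * e
  cmd <- min(max(raw, cfg$min_sweep), cfg$max_sweep)
  state$last_error <- e
  state$last_command <- cmd
  state$saturated <- raw != cmd
  list(command = cmd, state = state)
}

#' Fixed-sweep command (standard-of-care mode)
#'
#' In fixed-sweep mode the command is the configured constant flow,
#' independent of any measurement.
#'
#' @param cfg A [controller_config()] with `mode = "fixed_sweep"`.
#' @return Commanded sweep flow, L/min.
#' @export
fixed_sweep_command <- function(cfg) {
  if (cfg$mode != "fixed_sweep")
    stop("fixed_sweep_command applies only in fixed_sweep mode")
  cfg$fixed_sweep_flow
}

#' One inner flow-loop update: flow error to blower duty
#'
#' Nominal feedforward (the duty that would produce the commanded flow at
#' the assumed full-duty gain `ff_gain`) plus a PI trim on the flow error,
#' clamped to duty in `[0, 1]` with back-calculation anti-windup. The trim
#' integrates only while the (filter-lagged) flow error is inside
#' `int_band`, so large setpoint transients do not wind it up. A command
#' above the achievable maximum saturates the duty at 1 and raises the
#' `saturated` flag.
#'
#' @param command Commanded flow, L/min.
#' @param measured_flow Measured (possibly filtered) flow, L/min.
#' @param state List with `trim` (integral trim, duty units); use
#'   `list(trim = 0)` to start.
#' @param dt Update interval, s.
#' @param kp,ki Inner PI gains, duty/(L/min) and duty/(L/min s).
#' @param ff_gain Assumed flow at full duty, L/min.
#' @param int_band Flow-error magnitude below which the trim integrates,
#'   L/min.
#' @return List with `duty`, updated `state`, and `saturated`.
#' @export
inner_flow_loop <- function(command, measured_flow, state = list(trim = 0),
                            dt = 0.1, kp = 0.02, ki = 0.05, ff_gain = 7,
                            int_band = 0.15) {
  e <- command - measured_flow
  if (abs(e) < int_band) state$trim <- state$trim + ki * dt * e
  raw <- command / ff_gain + state$trim + kp * e
  duty <- min(max(raw, 0), 1)
  if (raw != duty) state$trim <- state$trim - (raw - duty)
  list(duty = duty, state = state, saturated = raw > 1)
}

#' Scale the outer proportional gain (aggressiveness knob)
#'
#' Reducing the proportional term trades a slower initial response for less
#' overshoot after a metabolic step; this helper exposes that trade-off.
#'
#' @param aggressiveness Positive factor applied to `kp` (1 = unchanged).
#' @param cfg A [controller_config()].
#' @return The modified configuration.
#' @export
tune_gains <- function(aggressiveness, cfg = controller_config()) {
  stopifnot(aggressiveness > 0)
  cfg$kp <- cfg$kp * aggressiveness
  cfg
}
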