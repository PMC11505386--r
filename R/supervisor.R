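# Blower-module safety logic: fault heuristics on the exhaust module's
# signals, latching fixed-sweep fallback, and the gas-embolism pressure
# guard.

#' Fresh supervisor status
#'
#' @param cfg A [supervisor_config()].
#' @return List with `mode` (`"feedback"` or `"fallback_fixed"`), `faults`
#'   (character set) and `latched`.
#' @export
new_supervisor_status <- function(cfg = supervisor_config()) {
  list(mode = "feedback", faults = character(0), latched = FALSE)
}

#' Scan recent signal history for exhaust-module faults
#'
#' Applies the fault heuristics to the recent (1 Hz) history of the sensed
#' EGCO2 and the suggested sweep flow:
#' * `suggestion_frozen` - suggestion varies less than `suggestion_eps` over
#'   its window (a non-responsive exhaust module), unless the suggestion is
#'   sitting on the min/max clamp (a saturated controller is legitimately
#'   constant);
#' * `egco2_frozen` - EGCO2 varies less than `egco2_eps` over its window;
#' * `egco2_out_of_range` / `suggestion_out_of_range` - instantaneous bound
#'   violations.
#' With less history than a heuristic's window, that heuristic stays quiet
#' (conservative).
#'
#' @param history `data.frame` with columns `time` (s), `egco2` (mmHg) and
#'   `suggestion` (L/min), most recent rows last.
#' @param status Supervisor status to update.
#' @param cfg A [supervisor_config()].
#' @param clamps Optional `c(min_sweep, max_sweep)` used to recognise a
#'   saturated (legitimately constant) suggestion.
#' @return Updated status with any new faults added.
#' @export
check_faults <- function(history, status = new_supervisor_status(),
                         cfg = supervisor_config(), clamps = NULL) {
  n <- length(history$time)
  if (n == 0) return(status)
  now <- history$time[n]
  flag <- function(f) status$faults <<- union(status$faults, f)

  if (history$egco2[n] < cfg$egco2_bounds[1] ||
      history$egco2[n] > cfg$egco2_bounds[2])
    flag("egco2_out_of_range")
  if (history$suggestion[n] < 0 || history$suggestion[n] > 20)
    flag("suggestion_out_of_range")

  if (now - history$time[1] >= cfg$egco2_window) {
    idx <- history$time > now - cfg$egco2_window
    if (diff(range(history$egco2[idx])) < cfg$egco2_eps)
      flag("egco2_frozen")
  }

  if (now - history$time[1] >= cfg$suggestion_window) {
    idx <- history$time > now - cfg$suggestion_window
    sug <- history$suggestion[idx]
    if (diff(range(sug)) < cfg$suggestion_eps) {
      at_clamp <- !is.null(clamps) &&
        (all(abs(sug - clamps[1]) < 1e-9) || all(abs(sug - clamps[2]) < 1e-9))
      if (!at_clamp) flag("suggestion_frozen")
    }
  }
  status
}

#' Arbitrate between the suggested sweep and the fallback default
#'
#' With no active faults the exhaust module's suggestion passes through.
#' Any fault latches the supervisor into fixed-sweep fallback at the
#' pre-specified default flow; the latch persists until faults are cleared
#' and the supervisor is manually re-armed (see [rearm()]).
#'
#' @param suggested Suggested sweep flow, L/min.
#' @param status Supervisor status.
#' @param cfg A [supervisor_config()].
#' @return List with `command` (L/min) and the updated `status`.
#' @export
arbitrate <- function(suggested, status = new_supervisor_status(),
                      cfg = supervisor_config()) {
  if (length(status$faults) > 0 || status$latched) {
    status$latched <- TRUE
    status$mode <- "fallback_fixed"
    list(command = cfg$default_sweep, status = status)
  } else {
    status$mode <- "feedback"
    list(command = suggested, status = status)
  }
}

#' Manually re-arm the supervisor after a latched fallback
#'
#' Clears the latch only if no faults remain active.
#'
#' @param status Supervisor status.
#' @return Updated status.
#' @export
rearm <- function(status) {
  if (length(status$faults) == 0) {
    status$latched <- FALSE
    status$mode <- "feedback"
  }
  status
}

#' Gas-embolism pressure guard
#'
#' Flags `overpressure` when the lung gas inlet pressure exceeds ambient by
#' more than the configured limit; while flagged, the sweep command is
#' additionally capped at the flow whose modelled inlet pressure equals the
#' limit (`limit / gas_resistance` under the linear pressure model).
#'
#' @param inlet_pressure Lung gas inlet pressure, mmHg (absolute).
#' @param ambient Ambient pressure, mmHg.
#' @param status Supervisor status.
#' @param cfg A [supervisor_config()].
#' @param gas_resistance Active lung gas-side resistance, mmHg/(L/min).
#' @return List with updated `status` and `cap` (L/min, `Inf` when no cap
#'   applies).
#' @export
pressure_guard <- function(inlet_pressure, ambient = 760,
                           status = new_supervisor_status(),
                           cfg = supervisor_config(), gas_resistance = 6) {
  over <- (inlet_pressure - ambient) > cfg$pressure_limit
  if (over) {
    status$faults <- union(status$faults, "overpressure")
    cap <- cfg$pressure_limit / gas_resistance
  } else {
    status$faults <- setdiff(status$faults, "overpressure")
    cap <- Inf
  }
  list(status = status, cap = cap)
}
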