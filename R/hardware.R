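# Actuator and sensor models: blower pair, flow sensor, side-stream CO2
# sensor with transport delay, and one/two-point calibration.

#' Steady-state blower flow at a given duty
#'
#' The blower pair is a duty-proportional constant-pressure source driving
#' the series combination of the lung's gas-side resistance and the source's
#' internal resistance shared over the active blowers:
#' `flow = duty * max_pressure / (gas_resistance + internal_resistance / count_active)`.
#'
#' @param duty Commanded duty cycle in `[0, 1]`.
#' @param blower A [blower_config()].
#' @param lung A [lung_config()].
#' @return Steady-state flow, L/min (0 if no blower is active).
#' @export
#' @examples
#' blower_steady_flow(1, blower_config(), lung_config("tall"))   # 7
#' blower_steady_flow(1, blower_config(), lung_config("short"))  # 14
blower_steady_flow <- function(duty, blower = blower_config(),
                               lung = lung_config("tall")) {
  if (any(duty < 0 | duty > 1)) stop("duty must be in [0, 1]")
  if (blower$count_active == 0) return(0 * duty)
  denom <- lung$gas_resistance + blower$internal_resistance / blower$count_active
  duty * blower$max_pressure / denom
}

#' First-order blower flow dynamics
#'
#' Relaxes the previous flow toward the steady-state flow for the commanded
#' duty with the blower's time constant.
#'
#' @inheritParams blower_steady_flow
#' @param dt Time step, s.
#' @param prev_flow Flow at the previous step, L/min.
#' @return Flow after `dt`, L/min.
#' @export
blower_flow <- function(duty, blower = blower_config(),
                        lung = lung_config("tall"), dt = 0.1, prev_flow = 0) {
  ss <- blower_steady_flow(duty, blower, lung)
  prev_flow + (ss - prev_flow) * (1 - exp(-dt / blower$time_constant))
}

#' Simulated mass-flow sensor reading(s)
#'
#' Adds Gaussian noise to the true flow. Raw readings are noisy (default SD
#' 0.25 L/min); a 10 s moving average at the default 100 Hz sample rate has
#' SD `flow_noise_sd / sqrt(rate * 10)` (about 0.008 L/min), which is the
#' amortised accuracy of the flow estimate.
#'
#' @param true_flow True flow, L/min (recycled against `n`).
#' @param sensor A [sensor_config()].
#' @param n Number of readings to draw.
#' @return Reading(s), L/min.
#' @export
read_flow <- function(true_flow, sensor = sensor_config(), n = length(true_flow)) {
  if (any(true_flow < 0)) stop("true_flow must be >= 0")
  true_flow + stats::rnorm(n, 0, sensor$flow_noise_sd)
}

#' Fresh (identity) CO2 sensor calibration state
#'
#' @return List with `gain_correction`, `offset_correction`, `calibrated`.
#' @export
new_calibration <- function() {
  list(gain_correction = 1, offset_correction = 0, calibrated = FALSE)
}

#' One-point CO2 sensor calibration
#'
#' The sensor is calibrated against a blood-gas analyser reference at a
#' single point (default 20 mmHg). Under the default gain-dominated error
#' model the correction is a pure gain: `reference / observed`; the offset
#' is assumed zero. This removes a multiplicative error exactly at every
#' pCO2.
#'
#' @param observed Sensor reading at the reference gas, mmHg (> 0).
#' @param reference Reference pCO2, mmHg.
#' @param cal Calibration state to update.
#' @return Updated calibration state with `calibrated = TRUE`.
#' @export
calibrate_one_point <- function(observed, reference = 20, cal = new_calibration()) {
  if (observed <= 0) stop("observed reading must be > 0")
  cal$gain_correction <- reference / observed
  cal$offset_correction <- 0
  cal$calibrated <- TRUE
  cal
}

#' Two-point CO2 sensor calibration
#'
#' Fits gain and offset through two (reference, observed) pairs.
#'
#' @param observed Sensor readings at the two reference gases, mmHg.
#' @param reference The two reference pCO2 values, mmHg.
#' @param cal Calibration state to update.
#' @return Updated calibration state.
#' @export
calibrate_two_point <- function(observed, reference = c(20, 40),
                                cal = new_calibration()) {
  stopifnot(length(observed) == 2, length(reference) == 2)
  if (abs(diff(observed)) < .Machine$double.eps)
    stop("observed readings must differ")
  g <- diff(reference) / diff(observed)
  cal$gain_correction <- g
  cal$offset_correction <- reference[1] - g * observed[1]
  cal$calibrated <- TRUE
  cal
}

#' Side-stream CO2 sensor reading
#'
#' The sensor reads the exhaust CO2 as a molar fraction of the stream and
#' normalises it by the sensing-chamber pressure; gain/offset errors and
#' Gaussian noise model the uncalibrated instrument, and the calibration
#' corrections are applied on top. Output is clipped at zero.
#'
#' @param pco2 True exhaust CO2 partial pressure, mmHg.
#' @param stream_pressure Total pressure of the exhaust stream, mmHg (> 0).
#' @param chamber_pressure Sensing-chamber pressure used for normalisation,
#'   mmHg (> 0).
#' @param cal Calibration state (see [calibrate_one_point()]).
#' @param sensor A [sensor_config()] carrying the error model.
#' @return Sensed EGCO2, mmHg.
#' @export
sense_egco2 <- function(pco2, stream_pressure = 760,
                        chamber_pressure = stream_pressure,
                        cal = new_calibration(), sensor = sensor_config()) {
  if (chamber_pressure <= 0) stop("chamber_pressure must be > 0")
  if (stream_pressure <= 0) stop("stream_pressure must be > 0")
  raw <- sensor$co2_gain_error * pco2 + sensor$co2_offset_error +
    stats::rnorm(length(pco2), 0, sensor$co2_noise_sd)
  fraction <- raw / stream_pressure
  reading <- fraction * chamber_pressure
  pmax(0, cal$gain_correction * reading + cal$offset_correction)
}

#' Gas transport delay from lung to sensor
#'
#' Plug-flow delay through the gas-path dead volume: `60 * dead_volume /
#' sweep` seconds. At low sweep the delay grows, which is one reason the
#' controller enforces a minimum flow.
#'
#' @param sweep Sweep flow, L/min.
#' @param dead_volume Gas path volume, L.
#' @return Delay, s (`Inf` at zero flow).
#' @export
transport_delay <- function(sweep, dead_volume = 0.05) {
  stopifnot(dead_volume > 0)
  ifelse(sweep > 0, 60 * dead_volume / sweep, Inf)
}

#' Plug-flow delay line for the EGCO2 signal
#'
#' Stateful buffer emulating the gas path between the lung outlet and the
#' CO2 sensing chamber. Each pushed parcel carries a gas volume and an EGCO2
#' value; the output is the value of the parcel currently at `dead_volume`
#' downstream, so with constant sweep `Q` the signal is delayed by exactly
#' `60 * dead_volume / Q` seconds (within one tick).
#'
#' @param dead_volume Gas path volume, L.
#' @param init_value Output before the first parcel has traversed the path.
#' @param capacity Maximum number of parcels retained.
#' @return A list with a `push(vol, value)` function returning the delayed
#'   value after appending a parcel of `vol` litres.
#' @export
plugflow_buffer <- function(dead_volume = 0.05, init_value = 0,
                            capacity = 400000L) {
  stopifnot(dead_volume > 0)
  cumv <- numeric(capacity)
  val <- numeric(capacity)
  head <- 0L
  tail <- 1L
  total <- 0
  push <- function(vol, value) {
    if (vol < 0) stop("parcel volume must be >= 0")
    head <<- head + 1L
    if (head > capacity) stop("plug-flow buffer capacity exceeded")
    total <<- total + vol
    cumv[head] <<- total
    val[head] <<- value
    target <- total - dead_volume
    if (target < 0) return(init_value)
    while (tail < head && cumv[tail] < target) tail <<- tail + 1L
    val[tail]
  }
  list(push = push)
}
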