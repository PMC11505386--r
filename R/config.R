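#' Membrane-lung (artificial lung) gas-side configuration
#'
#' The simulator supports two lung variants. The short variant has half the
#' gas-side resistance of the tall variant, so at full blower duty it admits
#' twice the sweep flow. `beta` is the gas-side equilibration parameter of
#' the single-transfer-unit exchange model (see [egco2_of_sweep()]);
#' `dead_volume` is the gas-path volume between lung outlet and CO2 sensor,
#' which sets the flow-dependent transport delay of the measurement.
#'
#' @param variant `"tall"` or `"short"`.
#' @param gas_resistance Gas-side flow resistance, mmHg per (L/min). Default
#'   6 for the tall variant and 3 for the short one (the blower calibration
#'   is chosen jointly so the tall lung tops out at 7 L/min).
#' @param beta Gas-side equilibration parameter, L/min.
#' @param dead_volume Gas path volume from lung to sensor, L.
#' @return A list of class `"lung_config"`.
#' @export
lung_config <- function(variant = c("tall", "short"),
                        gas_resistance = NULL,
                        beta = 1.2,
                        dead_volume = 0.05) {
  variant <- match.arg(variant)
  if (is.null(gas_resistance)) {
    gas_resistance <- if (variant == "tall") 6 else 3
  }
  stopifnot(gas_resistance > 0, beta > 0, dead_volume > 0)
  structure(list(variant = variant, gas_resistance = gas_resistance,
                 beta = beta, dead_volume = dead_volume),
            class = "lung_config")
}

#' Blower pair configuration
#'
#' Each blower is modelled as a duty-proportional constant-pressure source
#' feeding the lung's gas-side resistance through an internal resistance
#' shared across the active blowers; actual flow relaxes first-order toward
#' the steady-state value. With the default `internal_resistance = 0`, max
#' flow scales exactly inversely with lung resistance (7 L/min tall,
#' 14 L/min short).
#'
#' @param max_pressure Source pressure at 100% duty, mmHg.
#' @param internal_resistance Per-source internal resistance, mmHg/(L/min).
#' @param count_active Number of running blowers (0, 1 or 2).
#' @param time_constant First-order flow response time constant, s.
#' @return A list of class `"blower_config"`.
#' @export
blower_config <- function(max_pressure = 42, internal_resistance = 0,
                          count_active = 2, time_constant = 0.2) {
  stopifnot(max_pressure > 0, internal_resistance >= 0,
            count_active %in% 0:2, time_constant > 0)
  structure(list(max_pressure = max_pressure,
                 internal_resistance = internal_resistance,
                 count_active = count_active,
                 time_constant = time_constant),
            class = "blower_config")
}

#' Sensor noise / timing configuration
#'
#' @param co2_noise_sd Gaussian noise SD on the CO2 reading, mmHg.
#' @param co2_gain_error Multiplicative error of the uncalibrated CO2 sensor.
#' @param co2_offset_error Additive error of the uncalibrated CO2 sensor, mmHg.
#' @param flow_noise_sd Raw mass-flow sensor noise SD, L/min.
#' @param co2_sample_period CO2 sensor update period, s.
#' @param flow_sample_rate Flow sensor sample rate, Hz.
#' @param latency_s Fixed side-stream sampling latency of the CO2 path, s.
#' @return A list of class `"sensor_config"`.
#' @export
sensor_config <- function(co2_noise_sd = 0.3, co2_gain_error = 1,
                          co2_offset_error = 0, flow_noise_sd = 0.25,
                          co2_sample_period = 1, flow_sample_rate = 100,
                          latency_s = 1) {
  stopifnot(co2_noise_sd >= 0, flow_noise_sd >= 0, co2_gain_error > 0,
            co2_sample_period > 0, flow_sample_rate > 0, latency_s >= 0)
  structure(list(co2_noise_sd = co2_noise_sd, co2_gain_error = co2_gain_error,
                 co2_offset_error = co2_offset_error,
                 flow_noise_sd = flow_noise_sd,
                 co2_sample_period = co2_sample_period,
                 flow_sample_rate = flow_sample_rate, latency_s = latency_s),
            class = "sensor_config")
}

#' Outer-loop (EGCO2) and inner-loop (flow) controller configuration
#'
#' The outer loop is a velocity-form PI controller mapping EGCO2 error to a
#' sweep-flow command, clamped to `[min_sweep, max_sweep]`; clamping the
#' velocity form doubles as anti-windup. In `fixed_sweep` mode the command is
#' constant (`fixed_sweep_flow`), emulating standard-of-care systems without
#' feedback. The inner loop drives blower duty so the measured flow tracks
#' the command.
#'
#' Outer gains are a calibration (the device's are not reported): the defaults meet
#' the design requirement of reaching the target within 2 min and holding
#' +/-5 mmHg on the reference water scenario.
#'
#' @param mode `"fixed_egco2"` (feedback) or `"fixed_sweep"`.
#' @param target_egco2 Target EGCO2 (tEGCO2), mmHg.
#' @param fixed_sweep_flow Commanded flow in fixed-sweep mode, L/min.
#' @param kp,ki Outer PI gains, (L/min)/mmHg and (L/min)/(mmHg s).
#' @param kd Unused derivative stub (kept 0).
#' @param min_sweep,max_sweep Command clamps, L/min. The 0.25 L/min floor
#'   keeps gas moving past the CO2 sensor and bounds the loop delay.
#' @param update_period Outer-loop update period, s.
#' @param inner_kp,inner_ki Inner flow-loop PI trim gains, duty/(L/min) and
#'   duty/(L/min s).
#' @param inner_ff_gain Assumed full-duty flow for the inner-loop
#'   feedforward, L/min.
#' @param flow_filter_tau Time constant of the EMA filter applied to the
#'   noisy flow reading before the inner loop, s.
#' @return A list of class `"controller_config"`.
#' @export
controller_config <- function(mode = c("fixed_egco2", "fixed_sweep"),
                              target_egco2 = 20, fixed_sweep_flow = 1,
                              kp = 0.03, ki = 0.02, kd = 0,
                              min_sweep = 0.25, max_sweep = 7,
                              update_period = 1,
                              inner_kp = 0.02, inner_ki = 0.05,
                              inner_ff_gain = 7, flow_filter_tau = 0.8) {
  mode <- match.arg(mode)
  stopifnot(kp >= 0, ki >= 0, min_sweep >= 0, max_sweep > min_sweep,
            update_period > 0, target_egco2 > 0, fixed_sweep_flow >= 0)
  if (mode == "fixed_egco2" && min_sweep < 0.25)
    stop("min_sweep must be >= 0.25 L/min in feedback mode")
  structure(list(mode = mode, target_egco2 = target_egco2,
                 fixed_sweep_flow = fixed_sweep_flow, kp = kp, ki = ki,
                 kd = kd, min_sweep = min_sweep, max_sweep = max_sweep,
                 update_period = update_period, inner_kp = inner_kp,
                 inner_ki = inner_ki, inner_ff_gain = inner_ff_gain,
                 flow_filter_tau = flow_filter_tau),
            class = "controller_config")
}

#' Supervisor (blower-module safety logic) configuration
#'
#' The blower module treats the exhaust module's flow command as a
#' "suggestion": it watches for frozen or out-of-range signals and, on any
#' fault (or a patient-operated switch), latches into a pre-specified
#' fixed-sweep fallback until manually re-armed.
#'
#' Detection windows are longer than the worst-case measurement transport
#' delay at the minimum sweep flow (12 s at 0.05 L dead volume) so a slow
#' but healthy loop is not mistaken for a frozen one. The frozen-suggestion
#' check skips windows where the suggestion sits on the min/max clamp,
#' because a saturated controller legitimately emits a constant command.
#'
#' @param default_sweep Fallback fixed sweep flow, L/min.
#' @param suggestion_window,egco2_window Detection windows, s.
#' @param suggestion_eps Suggestion variation below which it counts as
#'   frozen, L/min.
#' @param egco2_eps EGCO2 variation below which it counts as frozen, mmHg.
#' @param egco2_bounds Plausible EGCO2 range (low, high), mmHg.
#' @param pressure_limit Allowed lung inlet pressure above ambient, mmHg
#'   (gas-embolism guard).
#' @param enabled Logical; disable to run the bare controller.
#' @return A list of class `"supervisor_config"`.
#' @export
supervisor_config <- function(default_sweep = 1, suggestion_window = 30,
                              egco2_window = 60, suggestion_eps = 0.01,
                              egco2_eps = 0.1, egco2_bounds = c(1, 100),
                              pressure_limit = 50, enabled = TRUE) {
  stopifnot(default_sweep >= 0.25, suggestion_window > 0, egco2_window > 0,
            length(egco2_bounds) == 2, egco2_bounds[1] < egco2_bounds[2],
            pressure_limit > 0)
  structure(list(default_sweep = default_sweep,
                 suggestion_window = suggestion_window,
                 egco2_window = egco2_window,
                 suggestion_eps = suggestion_eps, egco2_eps = egco2_eps,
                 egco2_bounds = egco2_bounds,
                 pressure_limit = pressure_limit, enabled = enabled),
            class = "supervisor_config")
}

#' Full simulator configuration with calibrated defaults
#'
#' Collects the plant, lung, hardware, controller, supervisor and
#' integration settings. Plant values the source experiments specify are
#' used directly (5 US gallons = 18.93 L reservoir, 2 L/min conditioning
#' air, 37 C / ambient 760 mmHg); values they do not specify (water CO2
#' solubility, blood dissociation constants, conditioning efficiency,
#' exchange parameter beta) are calibrated defaults, all exposed here.
#'
#' @param ... Named overrides of top-level sections (`plant`, `lung`,
#'   `blower`, `sensor`, `controller`, `supervisor`, `sim`); each replaces
#'   only the fields supplied.
#' @return Nested list of class `"ecco2r_config"`.
#' @export
#' @examples
#' cfg <- default_config(controller = list(target_egco2 = 30))
#' cfg$controller$target_egco2
default_config <- function(...) {
  cfg <- structure(list(
    plant = list(
      volume_l = 18.93,          # 5 US gallons
      alpha_water = 0.03,        # mmol/(L mmHg), water CO2 solubility ~37 C
      blood_k1 = 2.2, blood_k2 = 0.40,  # content = k1 * pCO2^k2, mmol/L
      efficiency_conditioning = 0.22,   # fraction of gas-liquid gap closed/pass
      mixing_volume_l = 0.05,    # liquid volume between conditioning lung and AL
      air_flow = 2,              # L/min, conditioning lung air
      ambient_mmHg = 760, temp_k = 310),
    lung = lung_config("tall"),
    blower = blower_config(),
    sensor = sensor_config(),
    controller = controller_config(),
    supervisor = supervisor_config(),
    sim = list(dt = 0.1, trace_hz = 1, warmup_s = 300,
               init_reservoir_pco2 = 20)
  ), class = "ecco2r_config")
  merge_config(cfg, list(...))
}

merge_config <- function(cfg, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg))
      stop("unknown config section: ", nm)
    ov <- overrides[[nm]]
    if (is.list(ov)) {
      bad <- setdiff(names(ov), names(cfg[[nm]]))
      if (length(bad))
        stop("unknown config key in '", nm, "': ", paste(bad, collapse = ", "))
      cfg[[nm]][names(ov)] <- ov
    } else {
      cfg[[nm]] <- ov
    }
  }
  cfg
}

#' Load a configuration file (YAML or JSON) over the defaults
#'
#' Missing keys take their default values; unknown keys are an error. The
#' fully resolved configuration is what [run_scenario()] records in the
#' trace's provenance attribute.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose top level uses
#'   the section names of [default_config()].
#' @return An `"ecco2r_config"` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- default_config()
  cfg <- merge_config(cfg, raw)
  validate_config(cfg)
  cfg
}

#' Validate a simulator configuration
#'
#' Checks positivity/range invariants across all sections; errors name the
#' offending key.
#'
#' @param cfg An `"ecco2r_config"` list.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  p <- cfg$plant
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg)
  chk(p$volume_l > 0, "plant$volume_l must be > 0")
  chk(p$alpha_water > 0, "plant$alpha_water must be > 0")
  chk(p$blood_k1 > 0 && p$blood_k2 > 0, "blood dissociation constants must be > 0")
  chk(p$efficiency_conditioning > 0 && p$efficiency_conditioning <= 1,
      "plant$efficiency_conditioning must be in (0, 1]")
  chk(p$mixing_volume_l >= 0, "plant$mixing_volume_l must be >= 0")
  chk(p$air_flow > 0, "plant$air_flow must be > 0")
  chk(p$ambient_mmHg > 0 && p$temp_k > 0, "ambient/temperature must be > 0")
  chk(cfg$lung$gas_resistance > 0 && cfg$lung$beta > 0 && cfg$lung$dead_volume > 0,
      "lung parameters must be > 0")
  chk(cfg$blower$count_active %in% 0:2, "blower$count_active must be 0, 1 or 2")
  chk(cfg$controller$min_sweep < cfg$controller$max_sweep,
      "controller clamps must satisfy min_sweep < max_sweep")
  chk(cfg$sim$dt > 0, "sim$dt must be > 0")
  chk(cfg$sim$trace_hz > 0, "sim$trace_hz must be > 0")
  invisible(cfg)
}
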