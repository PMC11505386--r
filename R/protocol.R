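# Scenario definitions and the composed simulation loop: conditioning lung
# -> artificial lung -> transport delay -> sensor -> controller ->
# supervisor -> blower -> reservoir, on a fixed time step.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a test-circuit scenario
#'
#' A scenario is a metabolic challenge schedule applied to the circulating
#' carrier fluid plus the controller settings under test. Each schedule row
#' fixes the conditioning-lung CO2 flow for a duration (the in vitro
#' protocol used 4-minute steps). A warm-up period at the first schedule
#' level precedes the schedule so start-up transients do not contaminate the
#' transition metrics.
#'
#' @param name Scenario label.
#' @param fluid `"water"` or `"blood"`.
#' @param liquid_flow Carrier fluid flow, L/min (> 0).
#' @param schedule `data.frame` with columns `duration_s` (> 0) and
#'   `co2_flow` (L/min, >= 0).
#' @param controller A [controller_config()], or `NULL` to use the run
#'   configuration's controller.
#' @param fault_injections List of `list(time =, fault =)` entries; see
#'   [inject_fault()].
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @param init_reservoir_pco2 Initial reservoir pCO2, mmHg (`NULL`: config
#'   default).
#' @param warmup_s Warm-up duration, s (`NULL`: config default).
#' @return A list of class `"ecco2r_scenario"`.
#' @export
scenario <- function(name = "custom", fluid = c("water", "blood"),
                     liquid_flow = 1,
                     schedule = data.frame(duration_s = 240,
                                           co2_flow = 0.1),
                     controller = NULL, fault_injections = list(),
                     seed = 1L, init_reservoir_pco2 = NULL,
                     warmup_s = NULL) {
  fluid <- match.arg(fluid)
  stopifnot(liquid_flow > 0, all(schedule$duration_s > 0),
            all(schedule$co2_flow >= 0))
  structure(list(name = name, fluid = fluid, liquid_flow = liquid_flow,
                 schedule = schedule, controller = controller,
                 fault_injections = fault_injections, seed = as.integer(seed),
                 init_reservoir_pco2 = init_reservoir_pco2,
                 warmup_s = warmup_s),
            class = "ecco2r_scenario")
}

#' The reference in vitro scenario set
#'
#' Emulates the benchtop protocol:
#' * `target_10/20/30/40`: water at 1.0 L/min, conditioning CO2 stepped
#'   0.1 -> 0.2 -> 0.4 -> 0.8 L/min and back down, 4 min per step, feedback
#'   control at the named target;
#' * `fixed_sweep_1.0`, `fixed_sweep_2.0`: the same challenge without
#'   feedback (standard-of-care control arms);
#' * `flow_0.5/1.0/1.5/2.0`: water flow varied at target 20 mmHg, with the
#'   0.8 L/min conditioning level omitted;
#' * `blood`: whole-blood run at 1.0 L/min, target 20 mmHg, CO2 steps
#'   0.1/0.2/0.4 L/min.
#'
#' The schedule steps up and back down so both overshoot (after metabolic
#' increases) and undershoot (after decreases) are exercised.
#'
#' @param step_s Step duration, s.
#' @param seed Seed given to every scenario.
#' @return Named list of [scenario()] objects.
#' @export
reference_scenarios <- function(step_s = 240, seed = 1L) {
  updown <- function(levels) c(levels, rev(levels)[-1])
  sched <- function(levels) data.frame(duration_s = step_s,
                                       co2_flow = updown(levels))
  full <- c(0.1, 0.2, 0.4, 0.8)
  reduced <- c(0.1, 0.2, 0.4)
  out <- list()
  for (tgt in c(10, 20, 30, 40)) {
    out[[paste0("target_", tgt)]] <- scenario(
      name = paste0("target_", tgt), fluid = "water", liquid_flow = 1,
      schedule = sched(full),
      controller = controller_config(target_egco2 = tgt), seed = seed)
  }
  for (fs in c(1, 2)) {
    out[[sprintf("fixed_sweep_%.1f", fs)]] <- scenario(
      name = sprintf("fixed_sweep_%.1f", fs), fluid = "water",
      liquid_flow = 1, schedule = sched(full),
      controller = controller_config(mode = "fixed_sweep",
                                     fixed_sweep_flow = fs),
      seed = seed)
  }
  for (qf in c(0.5, 1, 1.5, 2)) {
    out[[sprintf("flow_%.1f", qf)]] <- scenario(
      name = sprintf("flow_%.1f", qf), fluid = "water", liquid_flow = qf,
      schedule = sched(reduced),
      controller = controller_config(target_egco2 = 20), seed = seed)
  }
  out[["blood"]] <- scenario(
    name = "blood", fluid = "blood", liquid_flow = 1,
    schedule = sched(reduced),
    controller = controller_config(target_egco2 = 20), seed = seed)
  out
}

#' Schedule a fault injection in a scenario
#'
#' Supported kinds: `"egco2_freeze"` (the sensed EGCO2 stops updating),
#' `"egco2_out_of_range"` (the sensed EGCO2 jumps to an implausible value),
#' `"suggestion_freeze"` (the suggested sweep stops updating),
#' `"patient_switch"` (the patient flags an error), and `"blower_failure"`
#' (one blower drops out). The fault takes effect from `time` (trace
#' timebase, seconds) onward.
#'
#' @param sc A [scenario()].
#' @param fault Fault kind.
#' @param time Onset time, s.
#' @return The scenario with the injection appended.
#' @export
inject_fault <- function(sc, fault, time) {
  kinds <- c("egco2_freeze", "egco2_out_of_range", "suggestion_freeze",
             "patient_switch", "blower_failure")
  if (!fault %in% kinds)
    stop("unknown fault kind: ", fault)
  sc$fault_injections <- c(sc$fault_injections,
                           list(list(time = time, fault = fault)))
  sc
}

#' Run a scenario through the composed simulator
#'
#' Fixed-step loop over the full circuit: conditioning-lung CO2 loading,
#' artificial-lung exchange at the current sweep, plug-flow transport delay
#' and side-stream latency to the CO2 sensor, the outer PI (or fixed-sweep)
#' command at the controller update period, supervisory fault checks,
#' arbitration and the pressure guard, inner flow loop and first-order
#' blower dynamics, and the well-mixed reservoir balance. Deterministic
#' given the scenario seed; the caller's RNG state is left untouched.
#'
#' @param sc A [scenario()].
#' @param config An [default_config()] list.
#' @param cal CO2 sensor calibration state applied to the readings.
#' @return `data.frame` trace (decimated to `config$sim$trace_hz`) with
#'   columns `time_s`, `egco2_true_mmHg`, `egco2_sensed_mmHg`,
#'   `sweep_cmd_lpm`, `sweep_act_lpm`, `pco2_pre_mmHg`, `pco2_post_mmHg`,
#'   `pco2_res_mmHg`, `mode`, `faults`; attributes `target`, `change_times`
#'   (s), `scenario` and `config` carry the provenance needed by the metrics
#'   functions.
#' @export
#' @examples
#' sc <- scenario(schedule = data.frame(duration_s = c(60, 60),
#'                                      co2_flow = c(0.1, 0.2)),
#'                warmup_s = 30)
#' tr <- run_scenario(sc)
#' head(tr)
run_scenario <- function(sc, config = default_config(),
                         cal = new_calibration()) {
  stopifnot(inherits(sc, "ecco2r_scenario"))
  validate_config(config)
  ctl <- sc$controller %||% config$controller
  plant <- config$plant
  lung <- config$lung
  blower <- config$blower
  sensor <- config$sensor
  sup_cfg <- config$supervisor
  dt <- config$sim$dt
  warmup <- sc$warmup_s %||% config$sim$warmup_s
  init_pco2 <- sc$init_reservoir_pco2 %||% config$sim$init_reservoir_pco2

  # preserve the caller's RNG state, then seed the run
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(sc$seed)

  durs <- c(if (warmup > 0) warmup, sc$schedule$duration_s)
  co2s <- c(if (warmup > 0) sc$schedule$co2_flow[1], sc$schedule$co2_flow)
  n <- as.integer(round(sum(durs) / dt))
  co2_at_tick <- rep(co2s, times = as.integer(round(durs / dt)))
  change_times <- (if (warmup > 0) warmup else 0) +
    cumsum(utils::head(sc$schedule$duration_s, -1))

  # faults active from their onset
  inj <- sc$fault_injections
  inj_time <- vapply(inj, function(x) x$time, numeric(1))
  inj_kind <- vapply(inj, function(x) x$fault, character(1))
  fault_on <- function(kind, t) any(inj_kind == kind & inj_time <= t)

  fluid <- sc$fluid
  ql <- sc$liquid_flow
  eff <- plant$efficiency_conditioning
  amb <- plant$ambient_mmHg

  res_content <- content_curve(fluid, init_pco2, plant$alpha_water,
                               plant$blood_k1, plant$blood_k2)
  # liquid mixing lag (conditioning-lung housing + tubing) between the
  # conditioning lung and the AL; first-order with tau = 60 * V_mix / Q_L
  mix_a <- if (plant$mixing_volume_l > 0)
    dt / (dt + 60 * plant$mixing_volume_l / sc$liquid_flow) else 1
  pre_lag <- conditioning_pass(init_pco2,
                               conditioning_inlet_pco2(plant$air_flow,
                                                       co2_at_tick[1], amb),
                               plant$efficiency_conditioning)

  feedback <- ctl$mode == "fixed_egco2"
  cmd <- if (feedback) ctl$min_sweep else ctl$fixed_sweep_flow
  sweep <- cmd
  inner_state <- list(trim = 0)
  ctl_state <- new_controller_state(ctl)
  ctl_state$last_command <- cmd
  flow_filt <- sweep
  ema_a <- dt / (dt + ctl$flow_filter_tau)

  pf <- plugflow_buffer(lung$dead_volume,
                        init_value = egco2_of_sweep(
                          conditioning_pass(init_pco2,
                            conditioning_inlet_pco2(plant$air_flow,
                                                    co2_at_tick[1], amb),
                            eff),
                          sweep, lung$beta))
  lat_n <- max(1L, as.integer(round(sensor$latency_s / dt)))
  lat_ring <- rep(environment(pf$push)$init_value, lat_n)
  lat_i <- 0L

  co2_every <- max(1L, as.integer(round(sensor$co2_sample_period / dt)))
  ctl_every <- max(1L, as.integer(round(ctl$update_period / dt)))
  egco2_sensed <- sense_egco2(lat_ring[1], amb, amb, cal, sensor)
  suggestion <- cmd

  sup <- new_supervisor_status(sup_cfg)
  hist_cap <- as.integer(ceiling(max(sup_cfg$egco2_window,
                                     sup_cfg$suggestion_window) /
                                 ctl$update_period)) + 2L
  h_time <- numeric(0); h_eg <- numeric(0); h_sg <- numeric(0)

  rec_every <- max(1L, as.integer(round(1 / (config$sim$trace_hz * dt))))
  n_rec <- n %/% rec_every
  r_t <- r_egt <- r_egs <- r_cmd <- r_act <- r_pre <- r_post <- r_res <-
    numeric(n_rec)
  r_mode <- character(n_rec); r_flt <- character(n_rec)
  ri <- 0L

  blower_live <- blower

  for (i in seq_len(n)) {
    t <- i * dt
    gas_in <- conditioning_inlet_pco2(plant$air_flow, co2_at_tick[i], amb)
    pco2_res <- pco2_from_content(fluid, res_content, plant$alpha_water,
                                  plant$blood_k1, plant$blood_k2)
    pre_inst <- conditioning_pass(pco2_res, gas_in, eff)
    pre_lag <- pre_lag + mix_a * (pre_inst - pre_lag)
    pre <- pre_lag
    al <- al_pass(pre, fluid, ql, sweep, lung$beta, amb, plant$temp_k,
                  plant$alpha_water, plant$blood_k1, plant$blood_k2)
    res_content <- reservoir_step(res_content, plant$volume_l, ql,
                                  al$content_out, dt)

    delayed <- pf$push(sweep * dt / 60, al$egco2)
    lat_i <- lat_i %% lat_n + 1L
    sensed_input <- lat_ring[lat_i]   # value from latency_s ago
    lat_ring[lat_i] <- delayed

    if (i %% co2_every == 0L) {
      if (fault_on("egco2_freeze", t)) {
        # sensor output frozen: keep previous reading
      } else if (fault_on("egco2_out_of_range", t)) {
        egco2_sensed <- 150
      } else {
        egco2_sensed <- sense_egco2(sensed_input, amb, amb, cal, sensor)
      }
    }

    if (i %% ctl_every == 0L) {
      if (feedback) {
        if (!fault_on("suggestion_freeze", t)) {
          up <- pi_update(egco2_sensed, ctl, ctl_state)
          suggestion <- up$command
          ctl_state <- up$state
        }
      } else {
        suggestion <- fixed_sweep_command(ctl)
      }
      if (sup_cfg$enabled) {
        h_time <- c(h_time, t); h_eg <- c(h_eg, egco2_sensed)
        h_sg <- c(h_sg, suggestion)
        if (length(h_time) > hist_cap) {
          keep <- seq.int(length(h_time) - hist_cap + 1L, length(h_time))
          h_time <- h_time[keep]; h_eg <- h_eg[keep]; h_sg <- h_sg[keep]
        }
        sup <- check_faults(list(time = h_time, egco2 = h_eg,
                                 suggestion = h_sg),
                            sup, sup_cfg,
                            clamps = c(ctl$min_sweep, ctl$max_sweep))
        if (fault_on("patient_switch", t))
          sup$faults <- union(sup$faults, "patient_switch")
        guard <- pressure_guard(amb + lung$gas_resistance * sweep, amb,
                                sup, sup_cfg, lung$gas_resistance)
        sup <- guard$status
        arb <- arbitrate(suggestion, sup, sup_cfg)
        sup <- arb$status
        cmd <- min(arb$command, guard$cap)
      } else {
        cmd <- suggestion
      }
      if (fault_on("blower_failure", t) && blower_live$count_active == 2)
        blower_live$count_active <- 1
    }

    meas <- if (sensor$flow_noise_sd > 0)
      sweep + stats::rnorm(1, 0, sensor$flow_noise_sd) else sweep
    flow_filt <- flow_filt + ema_a * (meas - flow_filt)
    il <- inner_flow_loop(cmd, flow_filt, inner_state, dt,
                          ctl$inner_kp, ctl$inner_ki, ctl$inner_ff_gain)
    inner_state <- il$state
    sweep <- blower_flow(il$duty, blower_live, lung, dt, sweep)

    if (i %% rec_every == 0L) {
      ri <- ri + 1L
      r_t[ri] <- t; r_egt[ri] <- al$egco2; r_egs[ri] <- egco2_sensed
      r_cmd[ri] <- cmd; r_act[ri] <- sweep
      r_pre[ri] <- pre; r_post[ri] <- al$pco2_out; r_res[ri] <- pco2_res
      r_mode[ri] <- if (sup_cfg$enabled) sup$mode else
        if (feedback) "feedback" else "fixed_sweep"
      r_flt[ri] <- paste(sup$faults, collapse = ";")
      if (!all(is.finite(c(r_egt[ri], r_act[ri], r_res[ri]))))
        stop("simulation diverged (non-finite state) at t = ", t, " s")
    }
  }

  trace <- data.frame(time_s = r_t, egco2_true_mmHg = r_egt,
                      egco2_sensed_mmHg = r_egs, sweep_cmd_lpm = r_cmd,
                      sweep_act_lpm = r_act, pco2_pre_mmHg = r_pre,
                      pco2_post_mmHg = r_post, pco2_res_mmHg = r_res,
                      mode = r_mode, faults = r_flt,
                      stringsAsFactors = FALSE)
  attr(trace, "target") <- if (feedback) ctl$target_egco2 else NA_real_
  attr(trace, "change_times") <- change_times
  attr(trace, "scenario") <- sc
  attr(trace, "config") <- config
  class(trace) <- c("ecco2r_trace", "data.frame")
  trace
}

#' Write a trace to CSV (with a JSON provenance sidecar)
#'
#' The sidecar (`<path>.json`) records the resolved configuration, scenario
#' and change times so the run can be reproduced and the metrics recomputed
#' from the file alone.
#'
#' @param trace A trace from [run_scenario()].
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar too?
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  if (sidecar) {
    strip <- function(x) {
      if (is.list(x)) lapply(unclass(x), strip) else x
    }
    sc <- attr(trace, "scenario")
    meta <- list(target = attr(trace, "target"),
                 change_times = attr(trace, "change_times"),
                 scenario = strip(sc[setdiff(names(sc), "controller")]),
                 controller = strip(sc$controller %||%
                                      attr(trace, "config")$controller),
                 config = strip(attr(trace, "config")))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}

#' Read a trace CSV (restoring sidecar metadata when present)
#'
#' @param path CSV path written by [write_trace()] or any file with the same
#'   header.
#' @return An `"ecco2r_trace"` data.frame.
#' @export
read_trace <- function(path) {
  trace <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side, simplifyVector = TRUE)
    attr(trace, "target") <- if (is.null(meta$target)) NA_real_ else
      as.numeric(meta$target)
    attr(trace, "change_times") <- as.numeric(unlist(meta$change_times))
  }
  class(trace) <- c("ecco2r_trace", "data.frame")
  trace
}
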