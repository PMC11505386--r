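# Shared fixtures: noise-free configuration, a short challenge scenario, and
# an open-loop circuit integrator used as the fine-timestep oracle for the
# mass-balance checks.

quiet_config <- function(...) {
  default_config(sensor = list(co2_noise_sd = 0, flow_noise_sd = 0),
                 supervisor = list(enabled = FALSE), ...)
}

short_scenario <- function(target = 20, seed = 1, warmup_s = 60,
                           levels = c(0.1, 0.4), step_s = 240) {
  scenario(name = "short", fluid = "water", liquid_flow = 1,
           schedule = data.frame(duration_s = step_s, co2_flow = levels),
           controller = controller_config(target_egco2 = target),
           seed = seed, warmup_s = warmup_s)
}

# Open-loop circuit (fixed sweep, no controller, no noise): integrates the
# conditioning -> AL -> reservoir loop with the module operations and
# returns the content trajectory plus the integrated boundary fluxes.
integrate_circuit <- function(dt, total_s, sweep = 1, co2_flow = 0.2,
                              ql = 1, init_pco2 = 20, fluid = "water",
                              volume = 18.93, eff = 0.22, beta = 1.2,
                              alpha = 0.03) {
  n <- round(total_s / dt)
  gas_in <- conditioning_inlet_pco2(2, co2_flow, 760)
  content <- content_curve(fluid, init_pco2, alpha)
  influx <- removal <- 0
  for (i in seq_len(n)) {
    pco2_res <- pco2_from_content(fluid, content, alpha)
    pre <- conditioning_pass(pco2_res, gas_in, eff)
    al <- al_pass(pre, fluid, ql, sweep, beta, alpha = alpha)
    c_pre <- content_curve(fluid, pre, alpha)
    c_res <- content_curve(fluid, pco2_res, alpha)
    influx <- influx + ql * (c_pre - c_res) * dt / 60
    removal <- removal + al$removal * dt / 60
    content <- reservoir_step(content, volume, ql, al$content_out, dt)
  }
  list(content = content, influx = influx, removal = removal,
       volume = volume)
}

# Naive brute-force settling-time oracle (minutes; 0 if never diverged,
# NA if never re-settled). Scans every candidate band entry independently.
settle_oracle <- function(t, x, target, change_time, band = 5,
                          sustain_s = 3) {
  keep <- t >= change_time
  t <- t[keep]; e <- abs(x[keep] - target)
  div <- Inf
  for (k in seq_along(t)) if (e[k] > band) { div <- k; break }
  if (!is.finite(div)) return(0)
  for (k in seq_along(t)) {
    if (k <= div) next
    if (e[k] > band) next
    ok <- TRUE
    for (j in seq_along(t)) {
      if (t[j] >= t[k] && t[j] <= t[k] + sustain_s && e[j] > band) {
        ok <- FALSE; break
      }
    }
    if (ok) return((t[k] - t[div]) / 60)
  }
  NA_real_
}

# Minimal trace container for metric tests on constructed series.
fake_trace <- function(time_s, egco2, target = NA_real_,
                       change_times = NULL) {
  tr <- data.frame(time_s = time_s, egco2_true_mmHg = egco2,
                   egco2_sensed_mmHg = egco2)
  attr(tr, "target") <- target
  attr(tr, "change_times") <- change_times
  class(tr) <- c("ecco2r_trace", "data.frame")
  tr
}
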