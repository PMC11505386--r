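# Scenario definitions, the composed simulation loop, fault injection and
# trace I/O.

test_that("reference scenario set matches the benchtop protocol", {
  scs <- reference_scenarios()
  # varying-target runs: 4-min steps up and back down through 4 CO2 levels
  s <- scs$target_20
  expect_equal(nrow(s$schedule), 7)
  expect_true(all(s$schedule$duration_s == 240))
  expect_equal(s$schedule$co2_flow, c(0.1, 0.2, 0.4, 0.8, 0.4, 0.2, 0.1))
  expect_equal(sort(vapply(scs[paste0("target_", c(10, 20, 30, 40))],
                           function(x) x$controller$target_egco2, 1)),
               c(10, 20, 30, 40), ignore_attr = TRUE)
  # control arms without feedback
  expect_equal(scs$fixed_sweep_1.0$controller$mode, "fixed_sweep")
  expect_equal(scs$fixed_sweep_2.0$controller$fixed_sweep_flow, 2)
  # varying-flow runs omit the 0.8 L/min level, 3 distinct CO2 levels
  expect_equal(sort(unique(scs$flow_1.5$schedule$co2_flow)), c(0.1, 0.2, 0.4))
  expect_equal(scs$flow_0.5$liquid_flow, 0.5)
  # blood run
  expect_equal(scs$blood$fluid, "blood")
  expect_equal(sort(unique(scs$blood$schedule$co2_flow)), c(0.1, 0.2, 0.4))
})

test_that("runs are bit-reproducible given the seed", {
  sc <- short_scenario(seed = 4)
  a <- run_scenario(sc)
  b <- run_scenario(sc)
  expect_identical(a, b)
  c_ <- run_scenario(short_scenario(seed = 5))
  expect_false(identical(a$egco2_sensed_mmHg, c_$egco2_sensed_mmHg))
})

test_that("the trace is well-formed and physically sane", {
  tr <- run_scenario(short_scenario())
  expect_s3_class(tr, "ecco2r_trace")
  expect_true(all(diff(tr$time_s) > 0))
  num <- vapply(tr[1:8], is.numeric, TRUE)
  expect_true(all(num))
  expect_true(all(is.finite(as.matrix(tr[1:8]))))
  # EGCO2 never exceeds the liquid pCO2 entering the lung (removal only)
  expect_true(all(tr$egco2_true_mmHg <= tr$pco2_pre_mmHg + 1e-9))
  # commands honour the clamps
  expect_true(all(tr$sweep_cmd_lpm >= 0.25 - 1e-9))
  expect_true(all(tr$sweep_cmd_lpm <= 7 + 1e-9))
})

test_that("with no CO2 source the sweep pins at the floor and EGCO2 decays", {
  # reservoir preloaded below target: nothing to remove, so the controller
  # rides the floor clamp while the conditioning lung strips the reservoir
  sc <- scenario(schedule = data.frame(duration_s = 600, co2_flow = 0),
                 init_reservoir_pco2 = 10, warmup_s = 0, seed = 3)
  tr <- run_scenario(sc, quiet_config())
  late <- tr[tr$time_s > 60, ]
  expect_true(all(late$sweep_cmd_lpm == 0.25))
  expect_lt(tail(tr$egco2_true_mmHg, 1), tr$egco2_true_mmHg[1])
  # monotone decay toward zero
  expect_true(all(diff(late$egco2_true_mmHg) <= 1e-9))
})

test_that("sweep rises with metabolic rate and falls back (feedback mode)", {
  tr <- run_scenario(reference_scenarios(seed = 2)$target_20)
  ct <- attr(tr, "change_times")
  bounds <- c(0, ct, max(tr$time_s) + 1)
  seg_mean <- vapply(seq_len(length(bounds) - 1), function(j) {
    idx <- tr$time_s > bounds[j] + 120 & tr$time_s <= bounds[j + 1]
    mean(tr$sweep_act_lpm[idx])
  }, numeric(1))
  # schedule is 0.1 0.2 0.4 0.8 0.4 0.2 0.1 (plus warm-up at 0.1 first)
  expect_true(all(diff(seg_mean[1:4]) > 0))   # rises with each step-up
  expect_true(all(diff(seg_mean[4:7]) < 0))   # falls with each step-down
})

test_that("fixed-sweep mode holds its command regardless of EGCO2", {
  sc <- scenario(schedule = data.frame(duration_s = c(120, 120),
                                       co2_flow = c(0.1, 0.8)),
                 controller = controller_config(mode = "fixed_sweep",
                                                fixed_sweep_flow = 1),
                 warmup_s = 0, seed = 1)
  tr <- run_scenario(sc)
  expect_true(all(tr$sweep_cmd_lpm == 1))
  expect_equal(attr(tr, "target"), NA_real_)
})

test_that("fault injection triggers fallback within one detection window", {
  base <- short_scenario(seed = 6, warmup_s = 60,
                         levels = c(0.2, 0.2), step_s = 240)
  cfg <- default_config()
  win <- cfg$supervisor$egco2_window

  frozen <- inject_fault(base, "egco2_freeze", 180)
  tr <- run_scenario(frozen, cfg)
  fb <- tr$time_s[tr$mode == "fallback_fixed"]
  expect_true(length(fb) > 0)
  expect_lte(min(fb), 180 + win + 1.5)
  # after fallback the command is the pre-specified default
  expect_true(all(tr$sweep_cmd_lpm[tr$mode == "fallback_fixed"] ==
                    cfg$supervisor$default_sweep))
  # sweep never collapses below the floor during the fault
  expect_true(all(tr$sweep_cmd_lpm >= min(cfg$supervisor$default_sweep, 0.25)))

  # patient switch: fallback at the next controller tick
  sw <- inject_fault(base, "patient_switch", 180)
  tr2 <- run_scenario(sw, cfg)
  fb2 <- tr2$time_s[tr2$mode == "fallback_fixed"]
  expect_lte(min(fb2), 181.5)

  # no injection: no fallback anywhere
  tr3 <- run_scenario(base, cfg)
  expect_true(all(tr3$mode == "feedback"))

  expect_error(inject_fault(base, "gremlins", 10), "unknown fault")
})

test_that("an out-of-range EGCO2 fault trips fallback immediately", {
  sc <- inject_fault(short_scenario(seed = 8, levels = c(0.2, 0.2)),
                     "egco2_out_of_range", 120)
  tr <- run_scenario(sc)
  fb <- tr$time_s[tr$mode == "fallback_fixed"]
  expect_lte(min(fb), 122)
})

test_that("trace CSV round-trips with its provenance sidecar", {
  tr <- run_scenario(short_scenario(seed = 9, levels = 0.2, step_s = 90,
                                    warmup_s = 30))
  path <- file.path(tempdir(), "trace.csv")
  write_trace(tr, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_trace(path)
  expect_equal(names(back)[1:10], names(as.data.frame(tr))[1:10])
  expect_equal(back$egco2_sensed_mmHg, tr$egco2_sensed_mmHg)
  expect_equal(attr(back, "target"), attr(tr, "target"))
  expect_equal(attr(back, "change_times"), attr(tr, "change_times"))
  unlink(c(path, paste0(path, ".json")))
})

test_that("configuration loading merges, validates and rejects unknown keys", {
  path <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("controller:", "  target_egco2: 30", "plant:",
               "  volume_l: 10"), path)
  cfg <- load_config(path)
  expect_equal(cfg$controller$target_egco2, 30)
  expect_equal(cfg$plant$volume_l, 10)
  expect_equal(cfg$plant$alpha_water, 0.03)  # defaults retained

  writeLines(c("plant:", "  not_a_key: 1"), path)
  expect_error(load_config(path), "not_a_key")
  writeLines(c("plant:", "  volume_l: -2"), path)
  expect_error(load_config(path), "volume_l")
  unlink(path)
})
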