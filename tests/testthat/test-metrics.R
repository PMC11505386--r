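# Settling time, overshoot and steady-state statistics, checked against
# closed forms and a brute-force oracle.

test_that("settling time: no divergence, closed-form decay, sustain rule", {
  # never leaves the band -> 0
  t <- 0:300
  tr <- fake_trace(t, 20 + 2 * sin(t / 10), target = 20)
  st <- settling_time(tr, 20, change_time = 100, window_end = 301)
  expect_identical(as.numeric(st), 0)

  # exponential return: jump to +8 at the change, tau = 20 s; the 5 mmHg
  # bound is crossed at 20*ln(8/5) ~ 9.40 s
  tt <- seq(0, 120, by = 0.01)
  x <- 20 + ifelse(tt >= 10, 8 * exp(-(tt - 10) / 20), 0)
  tr <- fake_trace(tt, x, target = 20)
  st <- settling_time(tr, 20, change_time = 10, window_end = 121)
  expect_equal(as.numeric(st) * 60, 20 * log(8 / 5), tolerance = 2e-3)
  expect_true(attr(st, "settled"))
  expect_equal(attr(st, "diverge_time"), 10)

  # a 2 s re-entry into the band is rejected by the 3 s sustain rule
  tt <- 0:60
  x <- rep(20, 61)
  x[tt >= 10 & tt <= 19] <- 28          # diverged
  x[tt %in% c(13, 14)] <- 21            # 2 s dip into the band
  x[tt >= 20] <- 20                     # settled for good
  tr <- fake_trace(tt, x, target = 20)
  st <- settling_time(tr, 20, change_time = 10, window_end = 61)
  expect_equal(as.numeric(st) * 60, 10)  # entry at t = 20, not t = 13

  # never re-settles -> NA with settled = FALSE
  tr <- fake_trace(0:100, rep(30, 101), target = 20)
  st <- settling_time(tr, 20, change_time = 5, window_end = 101)
  expect_true(is.na(st))
  expect_false(attr(st, "settled"))

  expect_error(settling_time(tr, 20, change_time = 500), "outside")
})

test_that("settling operator agrees with the brute-force oracle on random traces", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(60:200, 1)
    tt <- seq_len(n)
    a <- runif(1, 0, 12)
    tau <- runif(1, 3, 40)
    ct <- sample(10:30, 1)
    x <- 20 + ifelse(tt >= ct, a * exp(-(tt - ct) / tau), 0) +
      rnorm(n, 0, runif(1, 0, 2))
    tr <- fake_trace(tt, x, target = 20)
    got <- settling_time(tr, 20, change_time = ct, window_end = n + 1)
    want <- settle_oracle(tt, x, 20, ct)
    expect_equal(as.numeric(got), want,
                 info = sprintf("random trace %d", i))
  }
})

test_that("overshoot reports the peak excursion and its direction", {
  tr <- fake_trace(0:50, rep(20, 51), target = 20)
  expect_equal(as.numeric(overshoot(tr, 20, c(0, 50))), 0)

  x <- rep(20, 51); x[10:15] <- 28
  tr <- fake_trace(0:50, x, target = 20)
  ov <- overshoot(tr, 20, c(5, 30))
  expect_equal(as.numeric(ov), 8)
  expect_equal(attr(ov, "direction"), "overshoot")

  x <- rep(20, 51); x[10:15] <- 11
  ov <- overshoot(fake_trace(0:50, x, target = 20), 20, c(5, 30))
  expect_equal(as.numeric(ov), 9)
  expect_equal(attr(ov, "direction"), "undershoot")

  expect_error(overshoot(tr, 20, c(200, 300)), "empty")
})

test_that("segment statistics match hand-computed values and skip short segments", {
  # two segments: 0-199 s at 22, 200-399 s at 18, change at 200
  tt <- 0:399
  x <- c(rep(22, 200), rep(18, 200))
  tr <- fake_trace(tt, x, target = 20, change_times = 200)
  seg <- segment_stats(tr, 20, change_times = 200, exclude_s = 120)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$mean, c(22, 18))
  expect_equal(seg$sd, c(0, 0))
  expect_equal(seg$band_violation_fraction, c(0, 0))
  # retained windows start 120 s after each change
  expect_equal(seg$n, c(80, 80))

  expect_warning(
    seg2 <- segment_stats(fake_trace(0:250, rep(20, 251), 20,
                                     change_times = 50),
                          20, change_times = 50, exclude_s = 120),
    "skipped")
  expect_equal(nrow(seg2), 1)   # only the long second segment survives
})

test_that("whole-run SD bounds the post-settling SD on a stepped run", {
  tr <- run_scenario(short_scenario(seed = 13))
  whole <- whole_run_stats(tr)
  seg <- segment_stats(tr)
  expect_gte(whole$sd, max(seg$sd) * 0.999)
  # and the whole-run stats include the transition excursions
  expect_gte(whole$max, max(seg$max) - 1e-9)
})

test_that("compare_runs builds the controller-on vs fixed-sweep table", {
  tr <- run_scenario(short_scenario(seed = 14))
  cmp <- compare_runs(tr, list(same = tr))
  expect_equal(cmp$sd[1], cmp$sd[2])
  expect_equal(cmp$sd_ratio_vs_on[2], 1)
  expect_equal(cmp$run, c("on", "same"))

  other <- run_scenario(short_scenario(seed = 14, levels = c(0.1, 0.2)))
  expect_error(compare_runs(tr, list(bad = other)), "schedule")
})

test_that("metrics are stable under trace decimation", {
  sc <- short_scenario(seed = 15, levels = c(0.1, 0.4), step_s = 180)
  tr1 <- run_scenario(sc, default_config())
  tr10 <- run_scenario(sc, default_config(sim = list(trace_hz = 10)))
  ct <- attr(tr1, "change_times")
  s1 <- settling_time(tr1, 20, ct[1])
  s10 <- settling_time(tr10, 20, ct[1])
  # within one coarse (1 s) tick of each other
  expect_lte(abs(as.numeric(s1) - as.numeric(s10)) * 60, 1)
})

test_that("metrics_report bundles transitions, segments and whole-run stats", {
  tr <- run_scenario(short_scenario(seed = 16))
  rep <- metrics_report(tr)
  expect_s3_class(rep, "ecco2r_metrics")
  expect_equal(nrow(rep$transitions), 1)
  expect_equal(nrow(rep$segments), 2)
  expect_output(print(rep), "Whole run")
})
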