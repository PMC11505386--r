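# Step-response outcome definitions: settling time, overshoot/undershoot,
# steady-state segment statistics, and controller-on vs fixed-sweep
# comparison tables.

trace_signal <- function(trace, signal = c("sensed", "true")) {
  signal <- match.arg(signal)
  if (signal == "sensed") trace$egco2_sensed_mmHg else trace$egco2_true_mmHg
}

#' Settling time after a metabolic change
#'
#' Settling time is the time from when EGCO2 diverges from the target by
#' more than `band` after the change, until it is back within `band` and
#' stays there for at least `sustain_s`. The sustain interval is a
#' qualification of the band entry, not part of the duration (configurable
#' via `include_sustain`). If EGCO2 never leaves the band the settling time
#' is 0; if it never re-settles, `NA` is returned with attribute
#' `settled = FALSE`.
#'
#' @param trace A trace from [run_scenario()] (or [read_trace()]).
#' @param target Target EGCO2, mmHg (default: the trace's `target`
#'   attribute).
#' @param change_time Time of the metabolic change, s.
#' @param window_end Only samples before this time are considered (default:
#'   the next change or the trace end).
#' @param band Regulation band half-width, mmHg.
#' @param sustain_s Required in-band sustain, s.
#' @param include_sustain Count the sustain interval inside the settling
#'   time?
#' @param signal `"sensed"` (measured EGCO2, default) or `"true"`.
#' @return Settling time in minutes, with attributes `settled`,
#'   `diverge_time` and `settle_time` (s; `NA` where not applicable).
#' @export
settling_time <- function(trace, target = attr(trace, "target"), change_time,
                          window_end = NULL, band = 5, sustain_s = 3,
                          include_sustain = FALSE,
                          signal = c("sensed", "true")) {
  tt <- trace$time_s
  if (change_time < tt[1] || change_time > tt[length(tt)])
    stop("change_time outside the trace")
  if (is.null(window_end)) {
    ct <- attr(trace, "change_times")
    nxt <- ct[ct > change_time]
    window_end <- if (length(nxt)) nxt[1] else tt[length(tt)] + 1
  }
  idx <- which(tt >= change_time & tt < window_end)
  t <- tt[idx]
  e <- abs(trace_signal(trace, signal)[idx] - target)

  div <- which(e > band)
  if (!length(div)) {
    return(structure(0, settled = TRUE, diverge_time = NA_real_,
                     settle_time = NA_real_))
  }
  d0 <- div[1]
  inband <- e <= band
  k <- d0
  while (k <= length(t)) {
    k <- k + 1
    if (k > length(t)) break
    if (!inband[k]) next
    # candidate entry: require in-band for sustain_s (to the data available)
    sus <- which(t >= t[k] & t <= t[k] + sustain_s)
    if (all(inband[sus])) {
      entry <- if (include_sustain) t[k] + sustain_s else t[k]
      return(structure((entry - t[d0]) / 60, settled = TRUE,
                       diverge_time = t[d0], settle_time = entry))
    }
  }
  structure(NA_real_, settled = FALSE, diverge_time = t[d0],
            settle_time = NA_real_)
}

#' Settling time and peak excursion for every transition of a trace
#'
#' Applies [settling_time()] and [overshoot()] at each recorded metabolic
#' change.
#'
#' @inheritParams settling_time
#' @return `data.frame` with one row per transition: `change_time`,
#'   `settling_min`, `settled`, `settle_time`, `overshoot_mmHg`,
#'   `direction` (`"overshoot"` above target, `"undershoot"` below).
#' @export
transition_metrics <- function(trace, target = attr(trace, "target"),
                               band = 5, sustain_s = 3,
                               signal = c("sensed", "true")) {
  signal <- match.arg(signal)
  ct <- attr(trace, "change_times")
  if (is.null(ct) || !length(ct)) stop("trace has no recorded change times")
  ends <- c(ct[-1], max(trace$time_s) + 1)
  rows <- lapply(seq_along(ct), function(j) {
    st <- settling_time(trace, target, ct[j], ends[j], band, sustain_s,
                        signal = signal)
    w_end <- if (isTRUE(attr(st, "settled")) && !is.na(attr(st, "settle_time")))
      attr(st, "settle_time") else ends[j]
    ov <- overshoot(trace, target, c(ct[j], max(w_end, ct[j] + 1)),
                    signal = signal)
    data.frame(change_time = ct[j], settling_min = as.numeric(st),
               settled = attr(st, "settled"),
               settle_time = attr(st, "settle_time"),
               overshoot_mmHg = as.numeric(ov),
               direction = attr(ov, "direction"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Peak EGCO2 excursion in a transition window
#'
#' Maximum absolute deviation from the target within the window (change
#' time until settling or segment end); the direction attribute records
#' whether the peak lay above (`"overshoot"`) or below (`"undershoot"`) the
#' target.
#'
#' @inheritParams settling_time
#' @param window `c(start, end)` in seconds.
#' @return Peak |EGCO2 - target| in mmHg with attribute `direction`.
#' @export
overshoot <- function(trace, target = attr(trace, "target"), window,
                      signal = c("sensed", "true")) {
  idx <- which(trace$time_s >= window[1] & trace$time_s <= window[2])
  if (!length(idx)) stop("empty transition window")
  dev <- trace_signal(trace, signal)[idx] - target
  k <- which.max(abs(dev))
  structure(abs(dev[k]),
            direction = if (dev[k] >= 0) "overshoot" else "undershoot")
}

#' Steady-state statistics per schedule segment
#'
#' Mean, SD, max and min of EGCO2 per segment, excluding the first
#' `exclude_s` seconds after each metabolic change (steady-state
#' convention); segments shorter than `exclude_s` are skipped with a
#' warning. Also reports the fraction of retained samples outside the
#' `band` around the target.
#'
#' @inheritParams settling_time
#' @param change_times Metabolic change times, s (default: trace attribute).
#' @param exclude_s Seconds discarded at the start of each segment.
#' @return `data.frame` with one row per segment.
#' @export
segment_stats <- function(trace, target = attr(trace, "target"),
                          change_times = attr(trace, "change_times"),
                          exclude_s = 120, band = 5,
                          signal = c("sensed", "true")) {
  tt <- trace$time_s
  x <- trace_signal(trace, signal)
  starts <- c(tt[1], change_times)
  ends <- c(change_times, tt[length(tt)] + 1e-9)
  rows <- list()
  for (j in seq_along(starts)) {
    if (ends[j] - starts[j] <= exclude_s) {
      warning(sprintf("segment %d shorter than %g s: skipped", j, exclude_s))
      next
    }
    idx <- which(tt >= starts[j] + exclude_s & tt < ends[j])
    if (!length(idx)) next
    v <- x[idx]
    rows[[length(rows) + 1]] <- data.frame(
      segment = j, start_s = starts[j], end_s = ends[j], n = length(v),
      mean = mean(v), sd = stats::sd(v), max = max(v), min = min(v),
      band_violation_fraction = if (is.na(target)) NA_real_ else
        mean(abs(v - target) > band))
  }
  do.call(rbind, rows)
}

#' Whole-run EGCO2 statistics (transition periods included)
#'
#' @inheritParams settling_time
#' @return One-row `data.frame` with `mean`, `sd`, `max`, `min`.
#' @export
whole_run_stats <- function(trace, signal = c("sensed", "true")) {
  v <- trace_signal(trace, signal)
  data.frame(mean = mean(v), sd = stats::sd(v), max = max(v), min = min(v))
}

#' Compare a controller-on run against fixed-sweep control runs
#'
#' Builds a comparison table of whole-run EGCO2 statistics for the
#' feedback run and each fixed-sweep arm sharing the same challenge
#' schedule, plus the on/off SD ratio (the headline contrast between active
#' feedback and the standard of care).
#'
#' @param on_trace Feedback-mode trace.
#' @param off_traces Named list of fixed-sweep traces.
#' @param signal `"sensed"` or `"true"`.
#' @return `data.frame` with one row per run: `run`, `mean`, `sd`, `max`,
#'   `min`, `sd_ratio_vs_on`.
#' @export
compare_runs <- function(on_trace, off_traces,
                         signal = c("sensed", "true")) {
  signal <- match.arg(signal)
  sched_of <- function(tr) {
    sc <- attr(tr, "scenario")
    if (is.null(sc)) NULL else sc$schedule
  }
  ref <- sched_of(on_trace)
  for (tr in off_traces) {
    s <- sched_of(tr)
    if (!is.null(ref) && !is.null(s) && !identical(ref, s))
      stop("runs do not share the same challenge schedule")
  }
  rows <- c(list(on = on_trace), off_traces)
  out <- do.call(rbind, lapply(rows, whole_run_stats, signal = signal))
  out <- cbind(run = names(rows), out, row.names = NULL)
  out$sd_ratio_vs_on <- out$sd / out$sd[1]
  out
}

#' Full metrics report for a trace
#'
#' Bundles the per-transition settling/overshoot table, per-segment
#' steady-state statistics and the whole-run statistics.
#'
#' @inheritParams segment_stats
#' @return List of class `"ecco2r_metrics"` with elements `transitions`,
#'   `segments`, `whole_run`, `target`.
#' @export
metrics_report <- function(trace, target = attr(trace, "target"),
                           exclude_s = 120, band = 5,
                           signal = c("sensed", "true")) {
  signal <- match.arg(signal)
  trans <- if (!is.na(target) && length(attr(trace, "change_times")))
    transition_metrics(trace, target, band = band, signal = signal)
  else NULL
  structure(list(
    transitions = trans,
    segments = segment_stats(trace, target, exclude_s = exclude_s,
                             band = band, signal = signal),
    whole_run = whole_run_stats(trace, signal = signal),
    target = target), class = "ecco2r_metrics")
}

#' @export
print.ecco2r_metrics <- function(x, ...) {
  cat("EGCO2 regulation metrics (target:",
      if (is.na(x$target)) "none (fixed sweep)" else paste(x$target, "mmHg"),
      ")\n\nWhole run:\n")
  print(x$whole_run, row.names = FALSE)
  if (!is.null(x$transitions)) {
    cat("\nTransitions:\n")
    print(x$transitions, row.names = FALSE)
  }
  cat("\nSteady-state segments (120 s post-change excluded):\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}
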