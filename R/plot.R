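#' Plot a simulation trace (EGCO2 panel and sweep panel)
#'
#' Two stacked panels: sensed and true EGCO2 against the target band, and
#' commanded vs actual sweep flow, with metabolic change times marked.
#'
#' @param x A trace from [run_scenario()].
#' @param band Regulation band half-width drawn around the target, mmHg.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.ecco2r_trace <- function(x, band = 5, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  t_min <- x$time_s / 60
  target <- attr(x, "target")
  ct <- attr(x, "change_times")

  graphics::plot(t_min, x$egco2_sensed_mmHg, type = "l", col = "grey40",
                 xlab = "", ylab = "EGCO2 (mmHg)",
                 ylim = range(c(x$egco2_sensed_mmHg, x$egco2_true_mmHg,
                                target + c(-band, band)), na.rm = TRUE))
  graphics::lines(t_min, x$egco2_true_mmHg, col = "black")
  if (!is.na(target)) {
    graphics::abline(h = target, col = "red3")
    graphics::abline(h = target + c(-band, band), col = "red3", lty = 3)
  }
  if (length(ct)) graphics::abline(v = ct / 60, col = "steelblue", lty = 2)
  graphics::legend("topright", bty = "n", lty = 1,
                   col = c("grey40", "black"),
                   legend = c("sensed", "true"), cex = 0.8)

  graphics::plot(t_min, x$sweep_act_lpm, type = "l", col = "black",
                 xlab = "time (min)", ylab = "sweep (L/min)")
  graphics::lines(t_min, x$sweep_cmd_lpm, col = "grey50", lty = 2)
  if (length(ct)) graphics::abline(v = ct / 60, col = "steelblue", lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 2),
                   col = c("black", "grey50"),
                   legend = c("actual", "commanded"), cex = 0.8)
  invisible(x)
}
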