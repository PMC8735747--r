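#' Forest or funnel plot of a fitted meta-analysis
#'
#' Base-graphics forest plot (per-study and pooled odds ratios on a log
#' axis, squares sized by weight, pooled diamond) or funnel plot (log OR
#' vs standard error with pseudo confidence guide lines).
#'
#' @param x a `snp_meta` fit.
#' @param type `"forest"` (default) or `"funnel"`.
#' @param ... further graphical parameters passed to the base plot call.
#' @return `x`, invisibly.
#' @export
plot.snp_meta <- function(x, type = c("forest", "funnel"), ...) {
  type <- match.arg(type)
  sel <- x[[x$selected]]
  eff <- x$effects
  if (type == "forest") {
    k <- nrow(eff)
    ylim <- c(0, k + 2)
    xlim <- range(c(eff$ci_low, eff$ci_high, sel$ci_low, sel$ci_high, 1))
    graphics::plot(NA, xlim = xlim, ylim = ylim, log = "x",
                   xlab = "Odds ratio", ylab = "", yaxt = "n",
                   main = paste("Forest plot -", x$model, "model"), ...)
    graphics::axis(2, at = c(rev(seq_len(k)) + 1, 0.5),
                   labels = c(eff$study_id, "Pooled"), las = 1,
                   cex.axis = 0.8)
    for (i in seq_len(k)) {
      y <- k - i + 2
      graphics::segments(eff$ci_low[i], y, eff$ci_high[i], y)
      graphics::points(eff$or[i], y, pch = 15,
                       cex = 0.5 + 2 * sel$weights[i])
    }
    graphics::polygon(c(sel$ci_low, sel$or, sel$ci_high, sel$or),
                      c(0.5, 0.7, 0.5, 0.3), col = "grey40")
    graphics::abline(v = 1, lty = 2)
  } else {
    fd <- funnel_data(eff, sel, ci_level = x$ci_level)
    graphics::plot(fd$log_or, fd$se, ylim = rev(range(c(0, fd$se))),
                   xlab = "log OR", ylab = "Standard error", pch = 19,
                   main = paste("Funnel plot -", x$model, "model"), ...)
    se_grid <- seq(0, max(fd$se) * 1.05, length.out = 50)
    zc <- stats::qnorm(1 - (1 - x$ci_level) / 2)
    graphics::lines(sel$log_or - zc * se_grid, se_grid, lty = 2)
    graphics::lines(sel$log_or + zc * se_grid, se_grid, lty = 2)
    graphics::abline(v = sel$log_or)
  }
  invisible(x)
}
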