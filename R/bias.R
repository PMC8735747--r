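#' Egger's regression test for funnel-plot asymmetry
#'
#' Ordinary least-squares regression of the standard normal deviate
#' (log OR / SE) of each study on its precision (1/SE). In the absence of
#' small-study effects the intercept is zero; the test is a two-sided
#' t-test of the intercept with k - 2 degrees of freedom.
#'
#' @param effects data.frame from [study_effects()] (columns `log_or`, `se`).
#' @return An object of class `egger_test`: `intercept`, `intercept_se`,
#'   `slope`, `t`, `df`, `p`.
#' @export
#' @examples
#' egger_test(study_effects(glioma_rs2305948(), "allele"))
egger_test <- function(effects) {
  k <- nrow(effects)
  if (k < 3L) stop("Egger's test requires at least 3 studies",
                   call. = FALSE)
  precision <- 1 / effects$se
  if (diff(range(precision)) < sqrt(.Machine$double.eps) * max(precision))
    stop("all standard errors equal: precision is constant and the Egger regression is degenerate",
         call. = FALSE)
  snd <- effects$log_or / effects$se
  fit <- stats::lm(snd ~ precision)
  sm <- summary(fit)$coefficients
  structure(list(intercept = sm[1L, 1L], intercept_se = sm[1L, 2L],
                 slope = sm[2L, 1L], t = sm[1L, 3L], df = k - 2L,
                 p = sm[1L, 4L]),
            class = "egger_test")
}

#' @export
print.egger_test <- function(x, ...) {
  cat("Egger's regression test for funnel-plot asymmetry\n")
  cat(sprintf("  intercept = %.4f (SE %.4f), t = %.3f on %d df, p = %s\n",
              x$intercept, x$intercept_se, x$t, x$df, .fmt_p(x$p)))
  invisible(x)
}

#' Begg-Mazumdar rank correlation test for publication bias
#'
#' Kendall rank correlation between standardized study effects and their
#' variances. Effects are standardized against the fixed-effect pooled
#' value using the conditional variance v*_i = se_i^2 - 1/sum(1/se_j^2).
#' Significance uses the normal approximation
#' var(S) = k(k-1)(2k+5)/18 (tie-corrected when ties occur), with a
#' continuity correction |S| - 1 when k < 10.
#'
#' @param effects data.frame from [study_effects()].
#' @return An object of class `begg_test`: `tau`, `n_concordant`,
#'   `n_discordant`, `S`, `z`, `p`, `continuity_corrected`.
#' @export
#' @examples
#' begg_test(study_effects(glioma_rs2305948(), "allele"))
begg_test <- function(effects) {
  k <- nrow(effects)
  if (k < 2L) stop("Begg's test requires at least 2 studies",
                   call. = FALSE)
  v <- effects$se^2
  w <- 1 / v
  theta_fe <- sum(w * effects$log_or) / sum(w)
  v_star <- v - 1 / sum(w)
  t_i <- (effects$log_or - theta_fe) / sqrt(v_star)
  # enumerate pairs
  conc <- 0L; disc <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      s <- sign(t_i[j] - t_i[i]) * sign(v[j] - v[i])
      if (s > 0) conc <- conc + 1L else if (s < 0) disc <- disc + 1L
    }
  }
  S <- conc - disc
  tau <- S / (k * (k - 1) / 2)
  # tie correction over each ranking
  tie_term <- function(x) {
    t_counts <- table(x)
    sum(t_counts * (t_counts - 1) * (2 * t_counts + 5))
  }
  var_s <- (k * (k - 1) * (2 * k + 5) - tie_term(t_i) - tie_term(v)) / 18
  cc <- k < 10L
  z <- if (var_s <= 0) 0 else max(0, abs(S) - if (cc) 1 else 0) / sqrt(var_s)
  structure(list(tau = tau, n_concordant = conc, n_discordant = disc,
                 S = S, z = z, p = 2 * stats::pnorm(-z),
                 continuity_corrected = cc),
            class = "begg_test")
}

#' @export
print.begg_test <- function(x, ...) {
  cat("Begg-Mazumdar rank correlation test for publication bias\n")
  cat(sprintf("  Kendall tau = %.4f (S = %d: %d concordant, %d discordant)\n",
              x$tau, x$S, x$n_concordant, x$n_discordant))
  cat(sprintf("  z = %.3f%s, p = %s\n", x$z,
              if (x$continuity_corrected) " (continuity-corrected)" else "",
              .fmt_p(x$p)))
  invisible(x)
}

#' Funnel-plot data
#'
#' Returns the per-study points (log OR vs SE) together with the pseudo
#' confidence guide lines pooled +/- z * se, the data behind a standard
#' funnel plot.
#'
#' @param effects data.frame from [study_effects()].
#' @param pooled a `pool_result`, e.g. `snp_meta(...)$random`.
#' @param ci_level level for the guide lines, default 0.95.
#' @return A data.frame sorted by `se`: `study_id`, `log_or`, `se`,
#'   `guide_low`, `guide_high`.
#' @export
funnel_data <- function(effects, pooled, ci_level = 0.95) {
  stopifnot(nrow(effects) >= 1L, inherits(pooled, "pool_result"))
  zc <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- data.frame(study_id = effects$study_id, log_or = effects$log_or,
                    se = effects$se,
                    guide_low = pooled$log_or - zc * effects$se,
                    guide_high = pooled$log_or + zc * effects$se,
                    stringsAsFactors = FALSE)
  out <- out[order(out$se), , drop = FALSE]
  rownames(out) <- NULL
  out
}
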