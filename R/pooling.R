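#' Cochran's Q and I-squared heterogeneity statistics
#'
#' Cochran's Q is the weighted sum of squared deviations of study log odds
#' ratios from the fixed-effect pooled value, with inverse-variance weights
#' w_i = 1/se_i^2. Under homogeneity Q is chi-square with k-1 degrees of
#' freedom. I^2 = max(0, (Q - df)/Q) * 100 expresses the share of total
#' variation attributable to between-study heterogeneity.
#'
#' @param effects data.frame from [study_effects()] (columns `log_or`, `se`).
#' @return A list: `Q`, `df`, `p` (upper-tail chi-square p), `i2` (percent).
#' @export
#' @examples
#' heterogeneity(study_effects(glioma_rs2305948(), "allele"))
heterogeneity <- function(effects) {
  k <- nrow(effects)
  if (k < 2L) stop("heterogeneity requires at least 2 studies",
                   call. = FALSE)
  w <- 1 / effects$se^2
  theta_fe <- sum(w * effects$log_or) / sum(w)
  Q <- sum(w * (effects$log_or - theta_fe)^2)
  df <- k - 1L
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, df = df,
       p = stats::pchisq(Q, df = df, lower.tail = FALSE), i2 = i2)
}

# inverse-variance weighted pooling given per-study variances `v`
.pool_iv <- function(effects, v, method, ci_level, Q, df, p_q, i2, tau2) {
  w <- 1 / v
  wn <- w / sum(w)
  log_or <- sum(wn * effects$log_or)
  se <- 1 / sqrt(sum(w))
  z <- log_or / se
  zc <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(list(
    method = method, k = nrow(effects), log_or = log_or, se = se,
    or = exp(log_or),
    ci_low = exp(log_or - zc * se), ci_high = exp(log_or + zc * se),
    z = z, p = 2 * stats::pnorm(-abs(z)),
    Q = Q, df = df, p_q = p_q, i2 = i2, tau2 = tau2,
    weights = stats::setNames(wn, effects$study_id),
    ci_level = ci_level), class = "pool_result")
}

#' Fixed-effect (inverse-variance) pooled odds ratio
#'
#' Pools per-study log odds ratios with weights w_i = 1/se_i^2; the pooled
#' standard error is 1/sqrt(sum(w_i)). A single study passes through
#' unchanged. Heterogeneity statistics (Q, I^2) are attached when k >= 2
#' and reported as `NA` otherwise.
#'
#' @param effects data.frame from [study_effects()].
#' @param ci_level confidence level, default 0.95.
#' @return A `pool_result` list; see [snp_meta()] for the fields.
#' @export
pool_fixed <- function(effects, ci_level = 0.95) {
  k <- nrow(effects)
  if (k < 1L) stop("no studies to pool", call. = FALSE)
  het <- if (k >= 2L) heterogeneity(effects) else
    list(Q = NA_real_, df = NA_integer_, p = NA_real_, i2 = NA_real_)
  .pool_iv(effects, effects$se^2, "fixed", ci_level,
           het$Q, het$df, het$p, het$i2, tau2 = 0)
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Method-of-moments estimate of the between-study variance,
#' tau^2 = max(0, (Q - df) / C) with C = sum(w) - sum(w^2)/sum(w) computed
#' from the fixed-effect weights; the pooled estimate then uses
#' w*_i = 1/(se_i^2 + tau^2). When Q <= df, tau^2 truncates to zero and the
#' result coincides with [pool_fixed()]. A single study passes through.
#'
#' @inheritParams pool_fixed
#' @return A `pool_result` list; see [snp_meta()] for the fields.
#' @export
pool_random <- function(effects, ci_level = 0.95) {
  k <- nrow(effects)
  if (k < 1L) stop("no studies to pool", call. = FALSE)
  if (k == 1L) {
    out <- pool_fixed(effects, ci_level)
    out$method <- "random"
    return(out)
  }
  het <- heterogeneity(effects)
  w <- 1 / effects$se^2
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (het$Q - het$df) / C)
  .pool_iv(effects, effects$se^2 + tau2, "random", ci_level,
           het$Q, het$df, het$p, het$i2, tau2)
}

#' @export
print.pool_result <- function(x, ...) {
  cat(sprintf("%s-effect%s pooled OR (k = %d): %s\n",
              if (x$method == "fixed") "Fixed" else "Random",
              if (x$method == "random") "s (DerSimonian-Laird)" else
                " (inverse variance)",
              x$k, .fmt_or_ci(x$or, x$ci_low, x$ci_high)))
  cat(sprintf("  z = %.3f, p = %s\n", x$z, .fmt_p(x$p)))
  if (!is.na(x$Q))
    cat(sprintf("  Heterogeneity: Q = %.3f (df = %d, p = %s), I2 = %.1f%%, tau2 = %.4f\n",
                x$Q, x$df, .fmt_p(x$p_q), x$i2, x$tau2))
  invisible(x)
}

#' Meta-analysis of SNP case-control studies under a genetic model
#'
#' The central fitting function: derives per-study 2x2 tables under the
#' chosen genetic model, estimates per-study odds ratios, and pools them
#' under both the fixed-effect inverse-variance and the DerSimonian-Laird
#' random-effects models, with Cochran's Q / I^2 heterogeneity statistics.
#'
#' @param studies a [study_table()], e.g. from [read_studies()],
#'   [glioma_rs2305948()] or [simulate_studies()].
#' @param model one of [genetic_models()]; default `"allele"`.
#' @param method which pooled estimate the object reports as its
#'   coefficient: `"random"` (default - standard practice when
#'   heterogeneity is anticipated), `"fixed"`, or `"auto"` (random effects
#'   when the Q-test p < 0.10, fixed otherwise).
#' @param ci_level confidence level for all intervals, default 0.95.
#' @return An object of class `snp_meta` with components `studies`,
#'   `model`, `method`, `selected` (the method actually used), `effects`
#'   (per-study data.frame), and `fixed`/`random` pool results. Each pool
#'   result carries `or`, `ci_low`, `ci_high`, `log_or`, `se`, `z`, `p`,
#'   `Q`, `df`, `p_q`, `i2`, `tau2` and normalized `weights`.
#'   Methods: `print`, `summary`, `coef` (pooled log OR), `confint`,
#'   `weights`, `plot` (forest or funnel).
#' @export
#' @examples
#' fit <- snp_meta(glioma_rs2305948(), model = "allele")
#' fit
#' coef(fit)
#' confint(fit)
snp_meta <- function(studies, model = "allele",
                     method = c("random", "fixed", "auto"),
                     ci_level = 0.95) {
  method <- match.arg(method)
  model <- .match_model(model)
  stopifnot(inherits(studies, "study_table"))
  if (nrow(studies) < 1L) stop("empty study table", call. = FALSE)
  effects <- study_effects(studies, model, ci_level = ci_level)
  fixed <- pool_fixed(effects, ci_level = ci_level)
  random <- pool_random(effects, ci_level = ci_level)
  selected <- switch(method,
    random = "random", fixed = "fixed",
    auto = if (!is.na(random$p_q) && random$p_q < 0.10) "random" else "fixed")
  structure(list(studies = studies, model = model, method = method,
                 selected = selected, effects = effects,
                 fixed = fixed, random = random, ci_level = ci_level),
            class = "snp_meta")
}

#' @export
print.snp_meta <- function(x, ...) {
  cat("SNP case-control meta-analysis -", x$model, "model\n")
  cat("Studies:", nrow(x$effects), "  pooled by:", x$selected,
      if (x$selected == "random") "effects (DerSimonian-Laird)" else
        "effect (inverse variance)", "\n")
  sel <- x[[x$selected]]
  cat(sprintf("Pooled OR = %s, p = %s\n",
              .fmt_or_ci(sel$or, sel$ci_low, sel$ci_high), .fmt_p(sel$p)))
  if (!is.na(sel$Q))
    cat(sprintf("Heterogeneity: Q = %.3f (p = %s), I2 = %.1f%%, tau2 = %.4f\n",
                sel$Q, .fmt_p(sel$p_q), sel$i2, sel$tau2))
  invisible(x)
}

#' @export
summary.snp_meta <- function(object, ...) {
  structure(object, class = c("summary.snp_meta", "snp_meta"))
}

#' @export
print.summary.snp_meta <- function(x, ...) {
  print.snp_meta(x)
  sel <- x[[x$selected]]
  eff <- x$effects
  tab <- data.frame(study = eff$study_id,
                    OR = round(eff$or, 2),
                    ci_low = round(eff$ci_low, 2),
                    ci_high = round(eff$ci_high, 2),
                    `weight%` = round(100 * unname(sel$weights), 1),
                    check.names = FALSE)
  cat("\nPer-study estimates:\n")
  print(tab, row.names = FALSE)
  cat("\nFixed-effect result:\n"); print(x$fixed)
  cat("Random-effects result:\n"); print(x$random)
  invisible(x)
}

#' @export
coef.snp_meta <- function(object, ...) {
  sel <- object[[object$selected]]
  stats::setNames(sel$log_or, "log_or")
}

#' @export
confint.snp_meta <- function(object, parm, level = NULL, ...) {
  sel <- object[[object$selected]]
  zc <- stats::qnorm(1 - (1 - (level %||% object$ci_level)) / 2)
  m <- matrix(c(sel$log_or - zc * sel$se, sel$log_or + zc * sel$se),
              nrow = 1,
              dimnames = list("log_or", c("lower", "upper")))
  m
}

#' @export
weights.snp_meta <- function(object, ...) {
  object[[object$selected]]$weights
}

`%||%` <- function(a, b) if (is.null(a)) b else a
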