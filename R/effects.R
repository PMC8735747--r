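#' Odds ratio and Wald confidence interval from a 2x2 table
#'
#' Computes the cross-product odds ratio ad/bc with its log-scale standard
#' error sqrt(1/a + 1/b + 1/c + 1/d) and a Wald confidence interval. If any
#' cell of the table is zero, 0.5 is added to all four cells of that table
#' (Haldane-Anscombe continuity correction) before estimation and the
#' result is flagged `corrected`.
#'
#' @param tab numeric vector `c(a, b, c, d)` as returned by [derive_2x2()]:
#'   exposed cases, unexposed cases, exposed controls, unexposed controls.
#' @param ci_level confidence level, default 0.95.
#' @param study_id optional label carried into the result.
#' @return A one-row data.frame: `study_id`, `log_or`, `se`, `or`,
#'   `ci_low`, `ci_high`, `corrected`.
#' @export
#' @examples
#' study_effect(c(3, 155, 8, 144))   # Vasconcelos, homozygote model
study_effect <- function(tab, ci_level = 0.95, study_id = NA_character_) {
  stopifnot(length(tab) == 4L, all(tab >= 0), ci_level > 0, ci_level < 1)
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  a <- tab[1L]; b <- tab[2L]; c <- tab[3L]; d <- tab[4L]
  log_or <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  data.frame(study_id = study_id, log_or = log_or, se = se,
             or = exp(log_or),
             ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
             corrected = corrected, stringsAsFactors = FALSE)
}

#' Per-study effect estimates under a genetic model
#'
#' Derives the 2x2 table of every study in a study table under the chosen
#' genetic model and computes per-study odds ratios via [study_effect()].
#'
#' @param studies a [study_table()].
#' @param model one of [genetic_models()].
#' @param ci_level confidence level, default 0.95.
#' @return A data.frame with one row per study, in input order.
#' @export
#' @examples
#' study_effects(glioma_rs2305948(), "allele")
study_effects <- function(studies, model, ci_level = 0.95) {
  stopifnot(inherits(studies, "study_table"))
  model <- .match_model(model)
  out <- do.call(rbind, lapply(seq_len(nrow(studies)), function(i) {
    tab <- derive_2x2(.arm_counts(studies, i, "case"),
                      .arm_counts(studies, i, "control"), model)
    study_effect(tab, ci_level = ci_level, study_id = studies$study_id[i])
  }))
  rownames(out) <- NULL
  out
}
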