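#' Run the full meta-analysis pipeline
#'
#' Orchestrates every stage: input validation, control-group
#' Hardy-Weinberg screening, per-model pooled analysis (fixed and random
#' effects), subgroup analysis, leave-one-out sensitivity analysis, and
#' Egger/Begg publication-bias tests. Bias tests that cannot run (too few
#' studies) degrade to a warning recorded in the report rather than a
#' failure.
#'
#' @param input a [study_table()], a path to a delimited study file, or
#'   `NULL` for the bundled [glioma_rs2305948()] dataset.
#' @param models character vector of genetic models, or `"all"` (default).
#' @param subgroup_key metadata column for subgroup analysis, default
#'   `"subgroup"`; `NULL` skips subgrouping.
#' @param hwe_alpha control-group HWE exclusion threshold, default 0.01.
#' @param method pooling method reported, as in [snp_meta()].
#' @param ci_level confidence level, default 0.95.
#' @return An object of class `meta_report`: `provenance`, `options`,
#'   `hwe` (filter result), `studies` (retained table), and per-model
#'   entries under `results`, each holding the `snp_meta` fit, the
#'   `subgroup_report`, the `loo_report`, `egger`/`begg` results (or the
#'   warning text), and `funnel` data.
#' @export
#' @examples
#' rep <- run_pipeline(models = "allele", subgroup_key = "subgroup")
#' rep$results$allele$fit
run_pipeline <- function(input = NULL, models = "all",
                         subgroup_key = "subgroup", hwe_alpha = 0.01,
                         method = "random", ci_level = 0.95) {
  studies <- if (is.null(input)) glioma_rs2305948()
    else if (inherits(input, "study_table")) input
    else read_studies(input)
  if (identical(models, "all")) models <- genetic_models()
  models <- vapply(models, .match_model, character(1))

  hwe <- hwe_filter(studies, alpha = hwe_alpha)
  retained <- hwe$retained
  if (nrow(retained) == 0L)
    stop("no studies remain after HWE filtering", call. = FALSE)
  k <- nrow(retained)

  results <- lapply(models, function(m) {
    fit <- snp_meta(retained, model = m, method = method,
                    ci_level = ci_level)
    subgroup <- if (!is.null(subgroup_key) && k >= 1L)
      subgroup_analysis(retained, key = subgroup_key, model = m,
                        method = method, ci_level = ci_level) else NULL
    loo <- if (k >= 2L) leave_one_out(retained, model = m, method = method,
                                      ci_level = ci_level) else NULL
    egger <- tryCatch(egger_test(fit$effects),
                      error = function(e) conditionMessage(e))
    begg <- tryCatch(begg_test(fit$effects),
                     error = function(e) conditionMessage(e))
    list(model = m, fit = fit, subgroup = subgroup, loo = loo,
         egger = egger, begg = begg,
         funnel = funnel_data(fit$effects, fit[[fit$selected]],
                              ci_level = ci_level))
  })
  names(results) <- models
  structure(list(provenance = attr(studies, "provenance") %||% "unknown",
                 options = list(models = models,
                                subgroup_key = subgroup_key,
                                hwe_alpha = hwe_alpha, method = method,
                                ci_level = ci_level),
                 hwe = hwe, studies = retained, results = results),
            class = "meta_report")
}

.pool_row <- function(sel) {
  data.frame(p_q = sel$p_q, i2 = sel$i2,
             or = sel$or, ci_low = sel$ci_low, ci_high = sel$ci_high,
             p = sel$p)
}

#' Render a pipeline report as plain-text tables
#'
#' Formats the report in the layout conventional for genetic-association
#' meta-analyses: an overall table (model, heterogeneity p, I^2, effect
#' model, OR with CI, p) and a subgroup table, with odds ratios to two
#' decimals and p-values to three (values below 0.0005 printed as
#' "<.001"; single-study strata show "-" for heterogeneity).
#'
#' @param report a `meta_report` from [run_pipeline()].
#' @return Character vector of lines, invisibly printed by `cat`-style use;
#'   returned so callers can write it to a file.
#' @export
render_text <- function(report) {
  stopifnot(inherits(report, "meta_report"))
  lines <- character()
  add <- function(...) lines <<- c(lines, paste0(...))
  add("Meta-analysis report (", report$provenance, ")")
  add("Studies retained: ", nrow(report$studies),
      "; excluded by HWE filter: ", nrow(report$hwe$excluded))
  if (nrow(report$hwe$excluded) > 0L)
    for (i in seq_len(nrow(report$hwe$excluded)))
      add("  excluded ", report$hwe$excluded$study_id[i], " (HWE p = ",
          .fmt_p(report$hwe$excluded$p[i]), ")")
  add("")
  add(sprintf("%-20s %-8s %-7s %-6s %-20s %s",
              "Genetic model", "Het p", "I2(%)", "Model", "OR (95% CI)", "p"))
  for (m in names(report$results)) {
    fit <- report$results[[m]]$fit
    sel <- fit[[fit$selected]]
    add(sprintf("%-20s %-8s %-7s %-6s %-20s %s",
                paste(m, "model"),
                if (is.na(sel$p_q)) "-" else .fmt_p(sel$p_q),
                if (is.na(sel$i2)) "-" else sprintf("%.1f", sel$i2),
                toupper(substr(fit$selected, 1, 1)),
                .fmt_or_ci(sel$or, sel$ci_low, sel$ci_high),
                .fmt_p(sel$p)))
  }
  has_subgroup <- any(vapply(report$results,
                             function(r) !is.null(r$subgroup), logical(1)))
  if (has_subgroup) {
    add("")
    add(sprintf("%-20s %-12s %-8s %-7s %-6s %-20s %s",
                "Genetic model", "Subgroup", "Het p", "I2(%)", "Model",
                "OR (95% CI)", "p"))
    for (m in names(report$results)) {
      sg <- report$results[[m]]$subgroup
      if (is.null(sg)) next
      for (g in names(sg$groups)) {
        fit <- sg$groups[[g]]
        sel <- fit[[fit$selected]]
        add(sprintf("%-20s %-12s %-8s %-7s %-6s %-20s %s",
                    paste(m, "model"), g,
                    if (is.na(sel$p_q)) "-" else .fmt_p(sel$p_q),
                    if (is.na(sel$i2)) "-" else sprintf("%.1f", sel$i2),
                    toupper(substr(fit$selected, 1, 1)),
                    .fmt_or_ci(sel$or, sel$ci_low, sel$ci_high),
                    .fmt_p(sel$p)))
      }
    }
  }
  add("")
  add("Publication bias:")
  for (m in names(report$results)) {
    r <- report$results[[m]]
    eg <- if (is.character(r$egger)) r$egger else
      paste0("Egger p = ", .fmt_p(r$egger$p))
    bg <- if (is.character(r$begg)) r$begg else
      paste0("Begg p = ", .fmt_p(r$begg$p))
    add(sprintf("  %-14s %s; %s", paste(m, "model"), eg, bg))
  }
  lines
}

#' @export
print.meta_report <- function(x, ...) {
  cat(render_text(x), sep = "\n")
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Serializes every numeric result of a [run_pipeline()] report - HWE
#' p-values, per-study effects, fixed and random pooled results with
#' heterogeneity and weights, subgroup and leave-one-out tables, bias
#' tests, funnel data - at full precision (rounding happens only in
#' [render_text()]).
#'
#' @param report a `meta_report`.
#' @param path output file; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "meta_report"))
  pool_list <- function(sel) sel[c("method", "k", "log_or", "se", "or",
                                   "ci_low", "ci_high", "z", "p", "Q",
                                   "df", "p_q", "i2", "tau2", "weights")]
  body <- list(
    provenance = report$provenance,
    options = report$options,
    hwe = list(p = as.list(report$hwe$p), excluded = report$hwe$excluded),
    models = lapply(report$results, function(r) {
      fit <- r$fit
      list(model = r$model, selected = fit$selected,
           effects = fit$effects,
           fixed = pool_list(fit$fixed), random = pool_list(fit$random),
           subgroup = if (!is.null(r$subgroup))
             lapply(r$subgroup$groups, function(g)
               pool_list(g[[g$selected]])),
           leave_one_out = if (!is.null(r$loo)) r$loo$table,
           egger = if (!is.character(r$egger)) unclass(r$egger)
                   else list(warning = r$egger),
           begg = if (!is.character(r$begg)) unclass(r$begg)
                  else list(warning = r$begg),
           funnel = r$funnel)
    }))
  js <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}
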