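#' Subgroup meta-analysis by a metadata field
#'
#' Partitions the studies by the value of a metadata column (labels are
#' trimmed and compared case-insensitively, so "Non-Asian" and "non-asian"
#' form one stratum) and fits [snp_meta()] within each stratum as well as
#' overall. Single-study strata are reported as passthrough estimates with
#' heterogeneity fields `NA`.
#'
#' @param studies a [study_table()].
#' @param key metadata column to stratify on, default `"subgroup"`.
#' @param model one of [genetic_models()].
#' @param method,ci_level passed to [snp_meta()].
#' @return An object of class `subgroup_report`: list with `key`, `model`,
#'   `groups` (named list of `snp_meta` fits, one per stratum, in order of
#'   first appearance) and `overall` (the all-studies `snp_meta` fit).
#' @export
#' @examples
#' sg <- subgroup_analysis(glioma_rs2305948(), model = "recessive")
#' sg$groups$Asian
subgroup_analysis <- function(studies, key = "subgroup", model = "allele",
                              method = "random", ci_level = 0.95) {
  stopifnot(inherits(studies, "study_table"))
  if (!key %in% names(studies))
    stop("no such metadata column: ", key, call. = FALSE)
  raw <- as.character(studies[[key]])
  missing_val <- is.na(raw) | trimws(raw) == ""
  if (any(missing_val))
    stop("study '", studies$study_id[which(missing_val)[1L]],
         "' has no value for '", key, "'", call. = FALSE)
  norm <- tolower(trimws(raw))
  labels <- trimws(raw)[!duplicated(norm)]   # display label: first seen
  groups <- lapply(tolower(labels), function(g) {
    snp_meta(.subset_studies(studies, norm == g), model = model,
             method = method, ci_level = ci_level)
  })
  names(groups) <- labels
  structure(list(key = key, model = model, groups = groups,
                 overall = snp_meta(studies, model = model, method = method,
                                    ci_level = ci_level)),
            class = "subgroup_report")
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat("Subgroup meta-analysis by '", x$key, "' - ", x$model, " model\n",
      sep = "")
  for (g in names(x$groups)) {
    fit <- x$groups[[g]]
    sel <- fit[[fit$selected]]
    cat(sprintf("  %-12s k=%d  OR = %s  p = %s  I2 = %s\n", g, sel$k,
                .fmt_or_ci(sel$or, sel$ci_low, sel$ci_high), .fmt_p(sel$p),
                if (is.na(sel$i2)) "-" else sprintf("%.1f%%", sel$i2)))
  }
  sel <- x$overall[[x$overall$selected]]
  cat(sprintf("  %-12s k=%d  OR = %s  p = %s\n", "Overall", sel$k,
              .fmt_or_ci(sel$or, sel$ci_low, sel$ci_high), .fmt_p(sel$p)))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the meta-analysis k times, omitting one study each time, to
#' assess the influence of individual studies on the pooled estimate.
#'
#' @inheritParams subgroup_analysis
#' @return An object of class `loo_report`: list with `model`, `fits`
#'   (named list of `snp_meta` fits, name = omitted study), and `table`
#'   (data.frame of omitted_id, or, ci_low, ci_high - the data behind the
#'   usual sensitivity plot).
#' @export
#' @examples
#' leave_one_out(glioma_rs2305948(), model = "allele")$table
leave_one_out <- function(studies, model = "allele", method = "random",
                          ci_level = 0.95) {
  stopifnot(inherits(studies, "study_table"))
  k <- nrow(studies)
  if (k < 2L) stop("leave-one-out requires at least 2 studies",
                   call. = FALSE)
  fits <- lapply(seq_len(k), function(i) {
    snp_meta(.subset_studies(studies, -i), model = model, method = method,
             ci_level = ci_level)
  })
  names(fits) <- studies$study_id
  tab <- do.call(rbind, lapply(names(fits), function(id) {
    sel <- fits[[id]][[fits[[id]]$selected]]
    data.frame(omitted_id = id, or = sel$or, ci_low = sel$ci_low,
               ci_high = sel$ci_high, stringsAsFactors = FALSE)
  }))
  structure(list(model = model, fits = fits, table = tab),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat("Leave-one-out sensitivity analysis -", x$model, "model\n")
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  omit %-16s OR = %s\n", tab$omitted_id[i],
                .fmt_or_ci(tab$or[i], tab$ci_low[i], tab$ci_high[i])))
  invisible(x)
}
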