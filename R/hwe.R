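#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit test of observed genotype counts against the
#' Hardy-Weinberg expected proportions ((1-q)^2, 2q(1-q), q^2) at the
#' estimated mutant-allele frequency q. The statistic is compared to a
#' chi-square distribution with 1 degree of freedom (three genotype cells,
#' one estimated allele frequency), without continuity correction. An exact
#' test (complete enumeration of heterozygote counts conditional on the
#' allele count) is available as an alternative.
#'
#' @param g integer vector of length 3: counts of CC, CT, TT (normally the
#'   control arm of a case-control study).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return A list of class `hwe_test`: `chi2`, `df` (1), `p`, `q` (estimated
#'   T allele frequency), `method`. For the exact test `chi2` is `NA`.
#' @details The marker must be polymorphic in the group tested: at `q = 0`
#'   or `q = 1` the expected heterozygote count is zero and the test is
#'   undefined, so an error is raised rather than reporting p = 1.
#' @export
#' @examples
#' hwe_test(c(629, 173, 13))  # p ~= 0.781
hwe_test <- function(g, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(length(g) == 3L, all(g >= 0))
  n <- sum(g)
  if (n < 1) stop("empty group", call. = FALSE)
  q <- allele_frequency(g)
  if (q == 0 || q == 1)
    stop("monomorphic marker (q = ", q, "): HWE test undefined",
         call. = FALSE)
  if (method == "chisq") {
    expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    chi2 <- sum((g - expected)^2 / expected)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    p <- .hwe_exact_p(g)
  }
  structure(list(chi2 = chi2, df = 1L, p = p, q = q, method = method),
            class = "hwe_test")
}

# Exact HWE p: enumerate all heterozygote counts compatible with the
# observed minor-allele count, conditional distribution of Levene/Haldane;
# p sums probabilities <= that of the observed configuration.
.hwe_exact_p <- function(g) {
  n <- sum(g)
  n_t <- g[2L] + 2L * g[3L]          # mutant allele count
  n_rare <- min(n_t, 2L * n - n_t)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  log_prob <- vapply(hets, function(h) {
    rare_hom <- (n_rare - h) / 2
    com_hom <- n - h - rare_hom
    h * log(2) - lgamma(h + 1) - lgamma(rare_hom + 1) - lgamma(com_hom + 1)
  }, numeric(1))
  # normalise within the conditional sample space (constants cancel)
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  p_obs <- prob[match(g[2L], hets)]
  sum(prob[prob <= p_obs + 1e-12])
}

#' @export
print.hwe_test <- function(x, ...) {
  cat("Hardy-Weinberg equilibrium test (", x$method, ")\n", sep = "")
  cat("  T allele frequency q =", format(x$q, digits = 4), "\n")
  if (!is.na(x$chi2))
    cat("  chi-square =", format(x$chi2, digits = 4), "on", x$df, "df\n")
  cat("  p =", format.pval(x$p, digits = 3), "\n")
  invisible(x)
}

#' Filter studies by control-group Hardy-Weinberg equilibrium
#'
#' Applies the standard inclusion rule for genetic-association
#' meta-analysis: a study is excluded when its control genotype
#' distribution departs from Hardy-Weinberg equilibrium at `p < alpha`
#' (strict inequality, so `p == alpha` is retained). Only controls are
#' tested; departure there flags genotyping error, whereas departure in
#' cases is expected under true association.
#'
#' @param studies a [study_table()].
#' @param alpha exclusion threshold, default 0.01.
#' @param method test passed to [hwe_test()].
#' @return A list with `retained` (a [study_table()]), `excluded`
#'   (data.frame of study_id, p), and `p` (named vector of all control HWE
#'   p-values in input order).
#' @export
#' @examples
#' hwe_filter(glioma_rs2305948())  # all four retained
hwe_filter <- function(studies, alpha = 0.01, method = "chisq") {
  stopifnot(inherits(studies, "study_table"), alpha >= 0, alpha <= 1)
  k <- nrow(studies)
  if (k == 0L) {
    return(list(retained = studies,
                excluded = data.frame(study_id = character(), p = numeric()),
                p = stats::setNames(numeric(), character())))
  }
  p <- vapply(seq_len(k), function(i) {
    hwe_test(.arm_counts(studies, i, "control"), method = method)$p
  }, numeric(1))
  names(p) <- studies$study_id
  drop <- p < alpha
  list(retained = .subset_studies(studies, !drop),
       excluded = data.frame(study_id = studies$study_id[drop],
                             p = unname(p[drop])),
       p = p)
}
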