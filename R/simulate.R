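#' Configuration for the multi-study genotype-count simulator
#'
#' Describes a set of case-control studies of one biallelic SNP with a
#' known true per-allele odds ratio. Defaults emulate the structure of the
#' bundled glioma dataset: four studies, arm sizes in the few-hundred
#' range, a control T-allele frequency near 0.15, and a modest effect.
#'
#' @param k number of studies (>= 1), default 4.
#' @param n_cases,n_controls per-study arm sizes, scalar or length-k,
#'   default 400 per arm.
#' @param q control-population T-allele frequency, scalar or length-k,
#'   strictly inside (0, 1); default 0.15.
#' @param psi true per-allele odds ratio (> 0), default 1. Case genotype
#'   odds are tilted multiplicatively by `psi` per T allele (log-additive
#'   risk), so the allele-model analysis is correctly specified and `psi`
#'   is its estimand.
#' @param tau between-study standard deviation of log(psi) (>= 0),
#'   default 0.
#' @param seed integer seed; identical config + seed reproduces the data
#'   exactly.
#' @param subgroups optional character vector (scalar or length-k) of
#'   subgroup labels; default "Sim".
#' @return A list of class `sim_config` with all fields length-k expanded.
#' @export
sim_config <- function(k = 4, n_cases = 400, n_controls = 400, q = 0.15,
                       psi = 1, tau = 0, seed = 1, subgroups = "Sim") {
  stopifnot(k >= 1, all(n_cases >= 1), all(n_controls >= 1),
            all(q > 0), all(q < 1), psi > 0, tau >= 0)
  rep_k <- function(x) {
    if (length(x) == 1L) rep(x, k)
    else if (length(x) == k) x
    else stop("per-study field must have length 1 or k", call. = FALSE)
  }
  structure(list(k = as.integer(k),
                 n_cases = as.integer(rep_k(n_cases)),
                 n_controls = as.integer(rep_k(n_controls)),
                 q = rep_k(q), psi = psi, tau = tau,
                 seed = as.integer(seed),
                 subgroups = rep_k(as.character(subgroups))),
            class = "sim_config")
}

# deterministic per-study substream seed: adding a study never perturbs
# the draws of earlier studies
.substream_seed <- function(seed, i) {
  as.integer((as.double(seed) + 104729 * as.double(i)) %% 2147483647)
}

#' Simulate multi-study case-control genotype counts
#'
#' For study i, the true study log odds ratio is drawn as
#' log(psi_i) ~ Normal(log(psi), tau^2). Control genotype probabilities
#' follow Hardy-Weinberg proportions ((1-q)^2, 2q(1-q), q^2) at the
#' configured control allele frequency; case genotype probabilities are
#' the control probabilities tilted multiplicatively by psi_i^g for
#' g = 0, 1, 2 copies of T, renormalized. Genotype counts are drawn as
#' three-category multinomials per arm - jointly, not allele-wise, so
#' Hardy-Weinberg can be (and under association is) violated in cases.
#' Each study uses its own deterministic random substream derived from the
#' global seed.
#'
#' @param cfg a [sim_config()].
#' @return A [study_table()] with synthetic metadata.
#' @export
#' @examples
#' simulate_studies(sim_config(k = 4, psi = 1.5, seed = 42))
simulate_studies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- lapply(seq_len(cfg$k), function(i) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(.substream_seed(cfg$seed, i))
    psi_i <- exp(stats::rnorm(1, mean = log(cfg$psi), sd = cfg$tau))
    q <- cfg$q[i]
    p_control <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    p_case <- p_control * psi_i^(0:2)
    p_case <- p_case / sum(p_case)
    g_control <- as.integer(stats::rmultinom(1, cfg$n_controls[i], p_control))
    g_case <- as.integer(stats::rmultinom(1, cfg$n_cases[i], p_case))
    data.frame(study_id = sprintf("sim%02d", i), author = "synthetic",
               year = 2000L + i, subgroup = cfg$subgroups[i],
               case_cc = g_case[1L], case_ct = g_case[2L],
               case_tt = g_case[3L],
               control_cc = g_control[1L], control_ct = g_control[2L],
               control_tt = g_control[3L], stringsAsFactors = FALSE)
  })
  study_table(do.call(rbind, rows), provenance = "simulated")
}

#' Repeated simulation to characterize estimator behavior
#'
#' Runs simulate-then-analyze `n_reps` times and summarizes bias and
#' coverage for the per-allele log odds ratio and the between-study
#' variance, plus Q-test and pooled-test rejection rates. Replicate r uses
#' a seed derived deterministically from `cfg$seed` and r.
#'
#' @param cfg a [sim_config()].
#' @param n_reps number of replicates (>= 1).
#' @param model genetic model analyzed, default `"allele"`.
#' @param method pooling method, default `"random"`.
#' @param alpha level for the pooled-effect test, default 0.05.
#' @param q_alpha level for the heterogeneity Q test, default 0.10.
#' @return A list: `n_reps`, `mean_log_or`, `true_log_or`, `bias`,
#'   `coverage` (share of CIs covering log(psi)), `mean_tau2`,
#'   `reject_rate` (pooled test), `q_reject_rate`, and `log_or`/`tau2`
#'   replicate vectors.
#' @export
recover_parameters <- function(cfg, n_reps, model = "allele",
                               method = "random", alpha = 0.05,
                               q_alpha = 0.10) {
  stopifnot(inherits(cfg, "sim_config"), n_reps >= 1)
  true_log_or <- log(cfg$psi)
  log_or <- tau2 <- p <- p_q <- covered <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- .substream_seed(cfg$seed, 7919 * r)
    tab <- simulate_studies(cfg_r)
    fit <- snp_meta(tab, model = model, method = method)
    sel <- fit[[fit$selected]]
    log_or[r] <- sel$log_or
    tau2[r] <- sel$tau2
    p[r] <- sel$p
    p_q[r] <- if (is.na(sel$p_q)) 1 else sel$p_q
    covered[r] <- (log(sel$ci_low) <= true_log_or) &&
      (true_log_or <= log(sel$ci_high))
  }
  list(n_reps = n_reps, mean_log_or = mean(log_or),
       true_log_or = true_log_or, bias = mean(log_or) - true_log_or,
       coverage = mean(covered), mean_tau2 = mean(tau2),
       reject_rate = mean(p < alpha), q_reject_rate = mean(p_q < q_alpha),
       log_or = log_or, tau2 = tau2)
}
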