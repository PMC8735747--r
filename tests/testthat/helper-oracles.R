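# Brute-force / independent oracles used across the suite.

glioma <- glioma_rs2305948()

# study table as a bare data.frame (drop class and provenance) for
# field-for-field comparisons
plain_df <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  rownames(x) <- NULL
  x
}

# cross-product odds ratio computed directly from genotype counts,
# independent of derive_2x2/study_effect
oracle_or <- function(cases, controls, model) {
  cc <- 1; ct <- 2; tt <- 3
  f <- switch(model,
    allele = function(g) c(g[ct] + 2 * g[tt], 2 * g[cc] + g[ct]),
    dominant = function(g) c(g[tt] + g[ct], g[cc]),
    recessive = function(g) c(g[tt], g[ct] + g[cc]),
    heterozygote = function(g) c(g[ct], g[cc]),
    homozygote = function(g) c(g[tt], g[cc]))
  ca <- f(cases); co <- f(controls)
  (ca[1] * co[2]) / (ca[2] * co[1])
}

# Kendall S statistic by exhaustive pair enumeration
oracle_kendall_S <- function(x, y) {
  k <- length(x)
  S <- 0L
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  S
}

# DerSimonian-Laird pooling written independently (plain formulas)
oracle_dl <- function(yi, sei) {
  w <- 1 / sei^2
  theta <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - theta)^2)
  df <- length(yi) - 1
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  ws <- 1 / (sei^2 + tau2)
  est <- sum(ws * yi) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  list(est = est, se = se, Q = Q, tau2 = tau2)
}

# random genotype-count vector, never an empty arm
random_counts <- function(n = 200) {
  g <- as.integer(stats::rmultinom(1, n, c(0.6, 0.3, 0.1)))
  g
}

# fixture-like simulation conditions: the bundled studies' arm sizes and
# control allele frequencies
fixture_like_config <- function(psi = 1, tau = 0, seed = 1) {
  sim_config(k = 4,
             n_cases = c(205, 157, 756, 477),
             n_controls = c(205, 160, 815, 477),
             q = c(0.168, 0.219, 0.122, 0.131),
             psi = psi, tau = tau, seed = seed)
}
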