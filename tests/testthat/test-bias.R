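test_that("Egger intercept vanishes on a constructed symmetric funnel", {
  # pairs of effects equidistant above/below a common mean, mirrored precisions
  mu <- 0.4
  dev <- c(0.3, -0.3, 0.15, -0.15)
  se <- c(0.2, 0.2, 0.35, 0.35)
  eff <- data.frame(study_id = paste0("s", 1:4),
                    log_or = (mu + dev) , se = se)
  # symmetric in effect but snd/precision pairs must mirror: enforce by design
  eff$log_or <- mu + dev
  res <- egger_test(eff)
  expect_equal(res$intercept, 0, tolerance = 1e-10)

  # negating all effects flips the intercept sign
  eff2 <- study_effects(glioma, "allele")
  res_pos <- egger_test(eff2)
  eff2_neg <- eff2; eff2_neg$log_or <- -eff2_neg$log_or
  expect_equal(egger_test(eff2_neg)$intercept, -res_pos$intercept)
})

test_that("Egger regression solves the normal equations on a hand-worked 3-point design", {
  # precisions 1,2,3 with SNDs 1,2,3: exact line through origin, slope 1
  eff <- data.frame(study_id = c("a", "b", "c"),
                    log_or = c(1, 2, 3) / c(1, 2, 3),  # snd = log_or/se
                    se = 1 / c(1, 2, 3))
  eff$log_or <- c(1, 2, 3) * eff$se  # snd_i = i
  res <- suppressWarnings(egger_test(eff))  # exact fit: summary.lm warns
  expect_equal(res$intercept, 0, tolerance = 1e-12)
  expect_equal(res$slope, 1, tolerance = 1e-12)
  expect_equal(res$df, 1L)
})

test_that("Egger test agrees with metafor and the weighted-regression formulation", {
  skip_if_not_installed("metafor")
  for (m in genetic_models()) {
    eff <- study_effects(glioma, m)
    got <- egger_test(eff)
    ref <- metafor::regtest(metafor::rma(yi = eff$log_or, sei = eff$se,
                                         method = "DL"), model = "lm")
    expect_equal(got$p, ref$pval, tolerance = 1e-8, info = m)
    # algebraically equivalent route: WLS of log OR on SE with weights
    # 1/SE^2 has the Egger intercept as its slope coefficient
    wls <- stats::lm(log_or ~ se, data = eff, weights = 1 / eff$se^2)
    expect_equal(got$intercept, unname(stats::coef(wls)[2]),
                 tolerance = 1e-10, info = m)
  }
})

test_that("Egger degenerate designs raise errors", {
  eff <- study_effects(glioma, "allele")
  expect_error(egger_test(eff[1:2, ]), "at least 3")
  const <- data.frame(study_id = c("a", "b", "c"),
                      log_or = c(0.1, 0.2, 0.3), se = c(0.2, 0.2, 0.2))
  expect_error(egger_test(const), "degenerate")
})

test_that("Begg statistic matches exhaustive pair enumeration for k <= 6", {
  set.seed(51)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    eff <- data.frame(study_id = paste0("s", 1:k),
                      log_or = stats::rnorm(k),
                      se = stats::runif(k, 0.1, 0.5))
    got <- begg_test(eff)
    # recompute the standardized effects independently and enumerate pairs
    v <- eff$se^2; w <- 1 / v
    t_i <- (eff$log_or - sum(w * eff$log_or) / sum(w)) / sqrt(v - 1 / sum(w))
    S <- oracle_kendall_S(t_i, v)
    expect_equal(got$S, S)
    expect_equal(got$tau, S / (k * (k - 1) / 2))
    expect_equal(got$n_concordant - got$n_discordant, S)
    # continuity-corrected normal approximation, var(S) = k(k-1)(2k+5)/18
    z <- max(0, abs(S) - 1) / sqrt(k * (k - 1) * (2 * k + 5) / 18)
    expect_equal(got$z, z)
    expect_equal(got$p, 2 * stats::pnorm(-z))
  }
})

test_that("Begg tau hits the perfect-discordance bound and monotone invariance", {
  # standardized effects strictly decreasing in variance
  eff <- data.frame(study_id = paste0("s", 1:4),
                    log_or = c(2, 1.2, 0.6, 0.1), se = c(0.1, 0.2, 0.3, 0.4))
  res <- begg_test(eff)
  expect_equal(res$tau, -1)
  expect_equal(res$n_discordant, 6L)

  # Kendall S depends on variances only through their ranks
  set.seed(52)
  t_i <- stats::rnorm(6); v <- stats::runif(6, 0.1, 1)
  expect_equal(oracle_kendall_S(t_i, v), oracle_kendall_S(t_i, v^3))
  expect_equal(oracle_kendall_S(t_i, v), oracle_kendall_S(t_i, exp(v)))

  expect_error(begg_test(eff[1, , drop = FALSE]), "at least 2")
})

test_that("no model shows significant Begg asymmetry on the glioma data", {
  for (m in genetic_models()) {
    eff <- study_effects(glioma, m)
    expect_gt(begg_test(eff)$p, 0.05)
  }
})

test_that("funnel data is sorted by SE with guide lines around the pooled value", {
  eff <- study_effects(glioma, "allele")
  pooled <- pool_random(eff)
  fd <- funnel_data(eff, pooled)
  expect_equal(nrow(fd), 4L)
  expect_false(is.unsorted(fd$se))
  expect_true(all(fd$se > 0.09 & fd$se < 0.21))
  expect_equal(fd$guide_high - fd$guide_low,
               2 * stats::qnorm(0.975) * fd$se)

  # single study: guide lines bracket it iff it equals the pooled value
  one <- eff[1, ]
  fd1 <- funnel_data(one, pooled)
  inside <- fd1$log_or >= fd1$guide_low & fd1$log_or <= fd1$guide_high
  expect_equal(inside,
               abs(one$log_or - pooled$log_or) <= stats::qnorm(0.975) * one$se)
})
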