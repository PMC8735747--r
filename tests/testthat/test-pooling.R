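test_that("heterogeneity statistics behave as defined", {
  # two identical effects: no dispersion
  same <- data.frame(study_id = c("a", "b"), log_or = c(0.3, 0.3),
                     se = c(0.1, 0.2))
  het <- heterogeneity(same)
  expect_equal(het$Q, 0)
  expect_equal(het$i2, 0)
  expect_equal(het$df, 1L)

  expect_error(heterogeneity(same[1, ]), "at least 2")

  # all-studies allele model: strong heterogeneity driven by Vasconcelos
  het_al <- heterogeneity(study_effects(glioma, "allele"))
  expect_equal(round(het_al$p, 3), 0.029)
  expect_equal(round(het_al$i2, 1), 66.8)

  # Asian stratum is homogeneous under every model
  asian <- study_table(as.data.frame(glioma)[glioma$subgroup == "Asian", ])
  for (m in genetic_models()) {
    expect_equal(heterogeneity(study_effects(asian, m))$i2, 0,
                 info = m)
  }
})

test_that("fixed-effect pooling is an inverse-variance weighted mean", {
  # equal standard errors: pooled log OR is the arithmetic mean
  eq <- data.frame(study_id = c("a", "b"), log_or = c(0.2, 0.6),
                   se = c(0.25, 0.25))
  expect_equal(pool_fixed(eq)$log_or, 0.4)

  # single study passes through
  e1 <- study_effects(glioma, "allele")[1, ]
  p1 <- pool_fixed(e1)
  expect_equal(p1$or, e1$or)
  expect_equal(p1$ci_low, e1$ci_low)
  expect_equal(p1$ci_high, e1$ci_high)
  expect_true(is.na(p1$Q))

  # weights sum to one
  pf <- pool_fixed(study_effects(glioma, "dominant"))
  expect_equal(sum(pf$weights), 1, tolerance = 1e-12)
})

test_that("DerSimonian-Laird pooling matches the independent formula oracle", {
  for (m in genetic_models()) {
    eff <- study_effects(glioma, m)
    got <- pool_random(eff)
    want <- oracle_dl(eff$log_or, eff$se)
    expect_equal(got$log_or, want$est, info = m)
    expect_equal(got$se, want$se, info = m)
    expect_equal(got$tau2, want$tau2, info = m)
    expect_equal(got$Q, want$Q, info = m)
  }
})

test_that("DerSimonian-Laird pooling agrees with metafor on every model", {
  skip_if_not_installed("metafor")
  for (m in genetic_models()) {
    eff <- study_effects(glioma, m)
    got <- pool_random(eff)
    ref <- metafor::rma(yi = eff$log_or, sei = eff$se, method = "DL")
    expect_equal(got$log_or, unname(ref$b[1]), tolerance = 1e-10, info = m)
    expect_equal(got$ci_low, exp(ref$ci.lb), tolerance = 1e-8, info = m)
    expect_equal(got$ci_high, exp(ref$ci.ub), tolerance = 1e-8, info = m)
    expect_equal(got$tau2, ref$tau2, tolerance = 1e-10, info = m)
    expect_equal(got$i2, ref$I2, tolerance = 1e-6, info = m)
  }
})

test_that("random effects collapse to fixed effect when tau2 truncates to zero", {
  asian <- study_table(as.data.frame(glioma[glioma$subgroup == "Asian", ]))
  for (m in genetic_models()) {
    eff <- study_effects(asian, m)
    fe <- pool_fixed(eff); re <- pool_random(eff)
    expect_equal(re$tau2, 0, info = m)
    expect_identical(re$log_or, fe$log_or)
    expect_identical(re$se, fe$se)
    expect_identical(re$ci_low, fe$ci_low)
  }
})

test_that("pooled estimate is convex and equivariant under negation", {
  set.seed(41)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    eff <- data.frame(study_id = paste0("s", 1:k),
                      log_or = stats::rnorm(k, 0, 0.5),
                      se = stats::runif(k, 0.05, 0.4))
    for (pool in list(pool_fixed, pool_random)) {
      res <- pool(eff)
      expect_gte(res$log_or, min(eff$log_or) - 1e-12)
      expect_lte(res$log_or, max(eff$log_or) + 1e-12)
      neg <- eff; neg$log_or <- -neg$log_or
      res_neg <- pool(neg)
      expect_equal(res_neg$log_or, -res$log_or)
      expect_equal(res_neg$Q, res$Q)
      expect_equal(res_neg$i2, res$i2)
      expect_equal(res_neg$tau2, res$tau2)
    }
  }
})

test_that("snp_meta reports the published overall random-effects results", {
  printed <- list(
    allele       = c(1.20, 0.93, 1.54),
    dominant     = c(1.17, 0.93, 1.46),
    recessive    = c(1.72, 0.94, 3.15),
    heterozygote = c(1.11, 0.94, 1.30),
    homozygote   = c(1.74, 0.92, 3.29))
  for (m in names(printed)) {
    fit <- snp_meta(glioma, model = m, method = "random")
    sel <- fit$random
    expect_equal(round(c(sel$or, sel$ci_low, sel$ci_high), 2), printed[[m]],
                 info = m)
  }
  # headline p-value of the allele model
  expect_equal(round(snp_meta(glioma, "allele")$random$p, 3), 0.162)
})

test_that("auto method selects random effects only under significant Q", {
  auto_al <- snp_meta(glioma, "allele", method = "auto")     # p_q = .029
  expect_equal(auto_al$selected, "random")
  auto_het <- snp_meta(glioma, "heterozygote", method = "auto")  # p_q = .487
  expect_equal(auto_het$selected, "fixed")
})

test_that("coef, confint and weights methods are coherent with the fit", {
  fit <- snp_meta(glioma, "dominant")
  expect_equal(unname(coef(fit)), fit$random$log_or)
  ci <- confint(fit)
  expect_equal(exp(ci[1, "lower"]), fit$random$ci_low)
  expect_equal(exp(ci[1, "upper"]), fit$random$ci_high)
  expect_equal(sum(weights(fit)), 1, tolerance = 1e-12)
})
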