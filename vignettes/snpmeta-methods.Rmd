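---
title: "Methods: genotype-count meta-analysis in snpmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-count meta-analysis in snpmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The statistical problem

A candidate-gene case-control study of a biallelic SNP reports six
numbers: the genotype counts CC, CT, TT among cases and among controls
(C wild-type, T mutant). Several such studies of the same variant are
combined by (1) collapsing each study's counts to a 2×2 table under a
genetic inheritance model, (2) estimating a per-study odds ratio, and
(3) pooling the log odds ratios across studies. `snpmeta` implements
this pipeline with the estimator choices that are standard in the
field, and bundles the four published glioma case-control studies of
the VEGFR2 variant rs2305948 (`glioma_rs2305948()`) as a worked
dataset.

## Genetic models

Five collapsing rules are supported (`genetic_models()`). Writing a
study's case counts as (cc, ct, tt) with n = cc + ct + tt:

| model | exposed | unexposed | case denominator |
|---|---|---|---|
| allele | ct + 2·tt | 2·cc + ct | 2n |
| dominant | tt + ct | cc | n |
| recessive | tt | ct + cc | n |
| heterozygote | ct | cc | n − tt |
| homozygote | tt | cc | n − ct |

The allele model treats the 2n alleles of each arm as independent
observations; this is the conventional choice and is exact under HWE
within arms. The heterozygote and homozygote models drop the excluded
genotype silently — that is what "CT vs CC" means — and raise a
degenerate-table error only when an entire arm empties. Useful
identities, all covered by property tests: swapping case and control
arms inverts every model's OR; relabeling C and T (reversing the count
vector) inverts the allele-model OR; the dominant and recessive exposed
cells differ by exactly ct.

## Hardy–Weinberg screening

Departure of *control* genotype frequencies from HWE proportions
((1−q)², 2q(1−q), q²) is the standard proxy for genotyping error, so
`hwe_filter()` tests controls only — cases are expected to depart under
a true association. The default test (`hwe_test(method = "chisq")`) is
the 1-df Pearson chi-square with no continuity correction, the variant
whose p-values agree with those conventionally reported alongside such
study tables (on the bundled dataset: .274, .122, .781, .125). A
conditional exact test is available as `method = "exact"` but is not
the default. Exclusion uses the strict rule p < α with α = 0.01
(`hwe_alpha`), so a study at exactly α is retained. Monomorphic control
groups (q = 0 or 1) are an error rather than p = 1: the test statistic
is undefined there, and silently passing such a study would hide a data
problem.

## Per-study effects and zero cells

The per-study estimate is the cross-product odds ratio with log-scale
standard error √(1/a + 1/b + 1/c + 1/d) and a Wald interval on the log
scale (`ci_level` default 0.95, as virtually all reported intervals
are). If any cell of a table is zero, 0.5 is added to *all four cells
of that table only* (Haldane–Anscombe); the flag `corrected` records
this. The bundled dataset has no zero cells, so its results are
unaffected; the rule matters for sparse simulated data, where the
recessive and homozygote models routinely produce zero TT counts.

## Pooling and heterogeneity

Fixed-effect pooling is inverse-variance: weights 1/se², pooled SE
1/√Σw. Cochran's Q is computed with those fixed weights; I² =
max(0, (Q − df)/Q)·100. The random-effects estimator is
DerSimonian–Laird: τ² = max(0, (Q − df)/C) with C = Σw − Σw²/Σw, then
inverse-variance pooling with weights 1/(se² + τ²). The pooled test is
Wald z against the normal (no Knapp–Hartung adjustment), matching how
results in this literature are reported. Two consequences are asserted
as invariants: when Q ≤ df, τ² truncates to zero and the random-effects
result is bit-for-bit the fixed-effect result; and a single study
passes through unchanged, which is how single-study strata are
reported (heterogeneity fields `NA`, printed as "–").

`snp_meta()` always computes both pooled estimates and marks one as
selected. The default `method = "random"` mirrors the common practice
of reporting random effects throughout; `method = "auto"` applies the
Q-gated rule (random iff the Q-test p < 0.10). The 0.10 threshold is
the conventional one for heterogeneity screening.

## Subgroups and sensitivity

`subgroup_analysis()` partitions on any metadata column; labels are
trimmed and compared case-insensitively so that cosmetic variants of
the same stratum name do not split a group. No between-subgroup
heterogeneity test is computed. `leave_one_out()` refits on each
(k−1)-subset; with the bundled data, omitting the single non-Asian
study is by construction identical to the Asian-stratum analysis, which
the tests exploit as an oracle.

## Publication-bias tests

`egger_test()` is the classic formulation: unweighted OLS of the
standard normal deviate (log OR / se) on precision (1/se), with a
two-sided t test of the intercept on k − 2 df. It requires k ≥ 3 and
errors when all standard errors are equal (the design matrix is then
degenerate). An algebraically equivalent route — WLS of log OR on se
with weights 1/se², whose slope equals the Egger intercept — is used as
an independent check in the tests. `begg_test()` standardizes effects
against the fixed-effect pooled value using the conditional variance
se² − 1/Σw, enumerates all pairs for Kendall's S, and uses the normal
approximation var(S) = k(k−1)(2k+5)/18 (tie-corrected) with a
continuity correction |S| − 1 when k < 10, appropriate for the very
small k typical of these meta-analyses.

On the bundled glioma data both tests are non-significant for the
allele, dominant and heterozygote models, and Begg's test for all five;
Egger's regression, however, *is* significant under the recessive
(p ≈ .007) and homozygote (p ≈ .011) models, a behavior confirmed
against an independent implementation. With k = 4 and one small study
whose effect points the opposite way, the Egger intercept is easily
driven to significance; this is a known small-k fragility of the test,
and a reason the package reports bias tests but never gates any
analysis on them.

## The simulator

`simulate_studies()` generates study tables with known truth. For study
i: log ψᵢ ~ Normal(log ψ, τ²); control genotype probabilities are HWE
at qᵢ; case genotype probabilities are the control probabilities tilted
by ψᵢ^g for g = 0, 1, 2 copies of T and renormalized (log-additive
risk, so the allele model is correctly specified and ψ is its
estimand — analyzing the same data under dominant or recessive models
deliberately exercises misspecification). Counts are drawn as
three-category multinomials per arm, jointly rather than allele-wise,
so HWE can be violated in cases as biology implies under association.

Defaults are fixture-like — k = 4 studies, 400 per arm, q = 0.15,
ψ = 1, τ = 0 — chosen once to match the bundled dataset's scale (arms
of 157–815, control allele frequencies 0.12–0.22). Each study draws
from its own substream, seeded as (seed + 104729·i) mod (2³¹ − 1), so
adding a study never perturbs earlier studies' draws, and the global
RNG state is restored afterwards. `recover_parameters()` wraps the
simulate–analyze loop and reports bias, CI coverage, mean τ̂², and
rejection rates.

What the simulator does *not* emulate: linkage disequilibrium,
covariates and confounding, population stratification, genotyping
error, or selective publication. Calibration results on simulated data
therefore validate the estimator arithmetic, not robustness to those
real-data features.

## Calibration results computed in the test suite

Two calibration checks run as part of the acceptance tests, at problem
sizes chosen to estimate the relevant rates with adequate Monte-Carlo
precision: (1) under the null (ψ = 1, τ = 0) at the bundled dataset's
study sizes and allele frequencies, the pooled-test type-I error over
2000 replicates falls within [0.03, 0.08]; (2) with ψ = 1.5, k = 20
and 2000 per arm, the mean pooled allele OR over 100 replicates is
within 5% of the truth. τ̂² is truncation-biased upward at τ = 0; this
is documented rather than asserted away.

## Degenerate inputs and numerical conventions

Empty arms, negative or fractional counts, duplicate study ids, and
declared sample sizes that contradict the genotype sums are validation
errors naming the study and field. Pipelines degrade rather than fail:
a single-study input yields passthrough estimates with all k ≥ 2
sections marked not applicable, and bias tests that cannot run are
recorded as warnings in the report. Rounding happens only at render
time — `render_text()` prints ORs to 2 decimals and p-values to 3 with
the "<.001" floor — while `report_json()` keeps full precision.

## Known limitations

Only the five classical genetic models are implemented (no
Cochran–Armitage trend test), pooling offers IV fixed and DL random
effects (no REML or Paule–Mandel, no meta-regression, no trim-and-fill),
and exact conditional odds ratios are not computed. These are deliberate
scope choices: the package covers the analysis pipeline that
genotype-count meta-analyses actually report.
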