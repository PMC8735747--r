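Package: snpmeta
Title: Meta-Analysis of Case-Control SNP Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of single nucleotide polymorphism (SNP)
    case-control association studies from per-study genotype counts. Derives
    two-by-two contingency tables under the five standard genetic inheritance
    models (allele, dominant, recessive, heterozygote, homozygote), screens
    control groups for Hardy-Weinberg equilibrium, computes per-study odds
    ratios with Haldane-Anscombe continuity correction, pools effects under
    fixed-effect inverse-variance and DerSimonian-Laird random-effects models
    with Cochran's Q and I-squared heterogeneity statistics, and provides
    subgroup analysis, leave-one-out sensitivity analysis, and Egger and Begg
    publication-bias tests. Includes a bundled dataset of four glioma
    case-control studies of the VEGFR2 polymorphism rs2305948 and a simulator
    for multi-study genotype-count data with known per-allele odds ratio and
    between-study heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), metafor, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
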