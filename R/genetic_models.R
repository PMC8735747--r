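#' Genetic inheritance models
#'
#' The five standard genetic models for a biallelic SNP with wild-type
#' allele C and mutant allele T:
#' \describe{
#'   \item{allele}{T vs C - each individual contributes two alleles}
#'   \item{dominant}{TT + CT vs CC}
#'   \item{recessive}{TT vs CT + CC}
#'   \item{heterozygote}{CT vs CC (TT individuals excluded)}
#'   \item{homozygote}{TT vs CC (CT individuals excluded)}
#' }
#'
#' @return Character vector of the five model names.
#' @export
genetic_models <- function() {
  c("allele", "dominant", "recessive", "heterozygote", "homozygote")
}

.match_model <- function(model) {
  match.arg(tolower(model), genetic_models())
}

# exposed/unexposed counts for one arm (cc, ct, tt) under a model
.arm_exposure <- function(g, model) {
  cc <- g[1L]; ct <- g[2L]; tt <- g[3L]
  switch(model,
    allele       = c(ct + 2L * tt, 2L * cc + ct),
    dominant     = c(tt + ct, cc),
    recessive    = c(tt, ct + cc),
    heterozygote = c(ct, cc),
    homozygote   = c(tt, cc))
}

#' Derive the 2x2 contingency table under a genetic model
#'
#' Collapses case and control genotype counts (CC, CT, TT) to an
#' exposed/unexposed by case/control table. Under the allele model the
#' 2n alleles of each arm are treated as independent observations; the
#' heterozygote and homozygote models drop the excluded genotype.
#'
#' @param cases,controls integer vectors of length 3: counts of CC, CT, TT.
#' @param model one of [genetic_models()].
#' @return Named numeric vector `c(a, b, c, d)`: exposed cases, unexposed
#'   cases, exposed controls, unexposed controls.
#' @export
#' @examples
#' derive_2x2(c(91, 46, 20), c(101, 48, 11), "allele")
derive_2x2 <- function(cases, controls, model) {
  model <- .match_model(model)
  stopifnot(length(cases) == 3L, length(controls) == 3L,
            all(cases >= 0), all(controls >= 0))
  ca <- .arm_exposure(cases, model)
  co <- .arm_exposure(controls, model)
  tab <- c(a = ca[1L], b = ca[2L], c = co[1L], d = co[2L])
  if (sum(ca) == 0 || sum(co) == 0)
    stop("degenerate table: no individuals enter the '", model,
         "' comparison in one arm", call. = FALSE)
  tab
}

#' Mutant (T) allele frequency from genotype counts
#'
#' @param g integer vector of length 3: counts of CC, CT, TT.
#' @return Frequency of the T allele in `[0, 1]`.
#' @export
#' @examples
#' allele_frequency(c(101, 48, 11))  # 70/320 = 0.21875
allele_frequency <- function(g) {
  stopifnot(length(g) == 3L, all(g >= 0))
  n <- sum(g)
  if (n < 1) stop("allele frequency undefined for an empty group",
                  call. = FALSE)
  (g[2L] + 2 * g[3L]) / (2 * n)
}
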