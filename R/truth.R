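#' True rate of inbreeding depression from segregating QTLs
#'
#' The expected decline of the trait mean per unit increase in the
#' inbreeding coefficient (the inbreeding load B) is the sum over
#' segregating QTLs of `2 d p q`, where `p` and `q` are the wild-type
#' and mutant allele frequencies and `d = a (h - 1/2)` is the dominance
#' effect.  With deleterious, partially recessive trait effects
#' (`a < 0`, `h < 1/2`) every `d > 0` and B is positive (directional
#' dominance).
#'
#' @param pop a `wf_population`.
#' @return The inbreeding load B (trait units per unit F).
#' @export
#' @examples
#' # one QTL, a = -1, h = 0.2, mutant frequency 0.2: B = 2*0.3*0.8*0.2
true_id_2dpq <- function(pop) {
  q <- qtl_genotypes(pop)
  if (ncol(q$geno) == 0) return(0)
  qf <- colMeans(q$geno) / 2           # mutant (derived) allele frequency
  d <- q$a * (q$h - 0.5)
  sum(2 * d * (1 - qf) * qf)
}

#' True inbreeding depression by forced homozygosity
#'
#' Makes every individual fully homozygous in expectation (each
#' heterozygous QTL value `a h` is replaced by the average of the two
#' homozygote values, `a / 2`) and returns the decline of the population
#' trait mean, i.e. the change from the current mean (F ~ 0) to the
#' fully inbred mean (F = 1).  Computing the heterozygote replacement in
#' expectation rather than by random allele fixing removes Monte Carlo
#' noise from a quantity that should match [true_id_2dpq()] almost
#' exactly; under exact Hardy-Weinberg genotype proportions the two are
#' identical.
#'
#' @param pop a `wf_population`.
#' @return The decline in the trait mean under complete inbreeding
#'   (same units as [true_id_2dpq()]).
#' @export
true_id_forced_homozygosity <- function(pop) {
  q <- qtl_genotypes(pop)
  if (ncol(q$geno) == 0) return(0)
  d <- q$a * (q$h - 0.5)
  # decline per heterozygous QTL copy is a*h - a/2 = d
  mean((q$geno == 1L) %*% cbind(d))
}

#' Both true-ID measures
#'
#' @param pop a `wf_population`.
#' @return list with `B_2dpq`, `B_forced` and `n_qtl`.
#' @export
true_id <- function(pop) {
  list(B_2dpq = true_id_2dpq(pop),
       B_forced = true_id_forced_homozygosity(pop),
       n_qtl = sum(pop$sites$is_qtl))
}
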