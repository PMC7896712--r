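#' Homozygous mutation load per individual
#'
#' Counts the loci at which an individual is homozygous for the derived
#' (mutant) allele:
#'
#' * `HML`: over all neutral segregating SNPs,
#' * `HML_MAF`: over neutral SNPs with minor-allele frequency at or
#'   below `maf_max` (the boundary is inclusive), and
#' * `HML_QTL`: over segregating QTLs.
#'
#' "Homozygous mutation" is read as homozygous for the derived allele,
#' not the minor allele (at low frequencies the two coincide); the
#' panel's `derived_is_minor` flags supply the orientation.
#'
#' @param panel a [marker_panel()] extracted with
#'   [extract_marker_panel()] (the `derived_is_minor` flags must be
#'   known).
#' @param qtl QTL genotypes from [qtl_genotypes()] on the same
#'   population.
#' @param maf_max inclusive MAF cutoff for `HML_MAF`.
#' @return data.frame with integer columns `HML`, `HML_MAF`, `HML_QTL`.
#' @export
hml_counts <- function(panel, qtl, maf_max = 0.05) {
  stopifnot(inherits(panel, "marker_panel"))
  if (anyNA(panel$derived_is_minor))
    stop("panel does not identify the derived allele; extract it from a population")
  x <- panel$genotypes
  dm <- panel$derived_is_minor
  derived_hom <- (x == 2L) & rep(dm, each = nrow(x)) |
                 (x == 0L) & rep(!dm, each = nrow(x))
  rare <- panel$p <= maf_max
  data.frame(
    HML = as.integer(rowSums(derived_hom)),
    HML_MAF = as.integer(rowSums(derived_hom[, rare, drop = FALSE])),
    HML_QTL = as.integer(rowSums(qtl$geno == 2L))
  )
}
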