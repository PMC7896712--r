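#' SNP-by-SNP genomic inbreeding estimators
#'
#' Per-individual estimators of the inbreeding coefficient from a dense
#' SNP panel, computed over all S markers with allele frequencies `p`
#' (by default the frequencies of the analyzed panel itself):
#'
#' * `f_I`:   `(1/S) sum_k (x_k - 2 p_k)^2 / (2 p_k (1 - p_k)) - 1`
#'   (VanRaden's second GRM diagonal; GCTA Fhat1),
#' * `f_II`:  `1 - (1/S) sum_k x_k (2 - x_k) / (2 p_k (1 - p_k))`
#'   (GCTA Fhat2),
#' * `f_III`: `(1/S) sum_k [x_k^2 - (1 + 2 p_k) x_k + 2 p_k^2] /
#'   (2 p_k (1 - p_k))` (correlation between uniting gametes; GCTA
#'   Fhat3), which weights homozygous genotypes by the inverse of their
#'   allele frequency, and
#' * `f_hom`: `1 - sum_k x_k (2 - x_k) / sum_k 2 p_k (1 - p_k)`
#'   (observed over expected heterozygote count; PLINK `--het`).
#'
#' All four take positive or negative values (excess or deficit of
#' homozygosity relative to Hardy-Weinberg proportions at the supplied
#' frequencies) and are invariant to relabelling alleles
#' (`x -> 2 - x`, `p -> 1 - p`).  When frequencies recorded at an
#' earlier reference generation are supplied via `p`, the estimators
#' measure identity by descent relative to that generation.
#'
#' `f_III_delta` is an algebraically equivalent reformulation of
#' `f_III` through per-genotype weights (`1/p` for minor homozygotes,
#' `1/(1-p)` for major homozygotes, 0 for heterozygotes); it exists as
#' an independent cross-check of the polynomial form.
#'
#' @param x a [marker_panel()] or an N x S dosage matrix (0/1/2);
#'   missing genotypes are an error (the formulas assume complete data).
#' @param p allele frequencies matching the dosage orientation; default
#'   are the panel frequencies.  Values outside `(0, 1)` are an error
#'   (a non-segregating site has no defined weight).
#' @return numeric vector of N per-individual estimates.
#' @seealso [roh_inbreeding()] for the ROH-based estimator.
#' @export
#' @examples
#' pnl <- marker_panel(matrix(c(0L, 1L, 1L, 2L), 4, 1), positions = 10)
#' f_I(pnl)
f_I <- function(x, p = NULL) {
  d <- .panel_data(x, p)
  (.rs(d$x^2, d$w) - 4 * .rs(d$x, d$p * d$w) + sum(4 * d$p^2 * d$w)) / d$S - 1
}

#' @rdname f_I
#' @export
f_II <- function(x, p = NULL) {
  d <- .panel_data(x, p)
  1 - (2 * .rs(d$x, d$w) - .rs(d$x^2, d$w)) / d$S
}

#' @rdname f_I
#' @export
f_III <- function(x, p = NULL) {
  d <- .panel_data(x, p)
  (.rs(d$x^2, d$w) - .rs(d$x, (1 + 2 * d$p) * d$w) + sum(2 * d$p^2 * d$w)) / d$S
}

#' @rdname f_I
#' @export
f_III_delta <- function(x, p = NULL) {
  d <- .panel_data(x, p)
  delta <- (d$x == 2) %*% cbind(1 / d$p) + (d$x == 0) %*% cbind(1 / (1 - d$p))
  as.vector(delta) / d$S - 1
}

#' @rdname f_I
#' @export
f_hom <- function(x, p = NULL) {
  d <- .panel_data(x, p)
  het <- rowSums(d$x == 1)
  1 - het / sum(2 * d$p * (1 - d$p))
}

#' All four SNP-by-SNP estimators as a table
#'
#' @inheritParams f_I
#' @return data.frame with columns `F_I`, `F_II`, `F_III`, `F_HOM`.
#' @export
f_estimates <- function(x, p = NULL) {
  data.frame(F_I = f_I(x, p), F_II = f_II(x, p),
             F_III = f_III(x, p), F_HOM = f_hom(x, p))
}

# shared validation/extraction for the estimators
.panel_data <- function(x, p) {
  if (inherits(x, "marker_panel")) {
    if (is.null(p)) p <- x$p
    x <- x$genotypes
  }
  x <- as.matrix(x)
  if (is.null(p)) stop("allele frequencies `p` are required with a plain matrix")
  if (length(p) != ncol(x)) stop("length(p) must equal the SNP count")
  if (ncol(x) == 0) stop("panel has no SNPs")
  if (anyNA(x)) stop("panel contains missing genotypes; estimators assume complete data")
  if (any(p <= 0 | p >= 1)) stop("allele frequencies must be strictly inside (0, 1)")
  storage.mode(x) <- "double"
  list(x = x, p = as.numeric(p), w = 1 / (2 * p * (1 - p)), S = ncol(x))
}

# rowSums of x scaled per column: (x * w) summed over columns
.rs <- function(x, w) as.vector(x %*% cbind(w))
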