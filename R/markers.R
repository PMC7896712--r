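#' Construct a marker panel
#'
#' A marker panel holds the minor-allele dosages of N individuals at S
#' biallelic SNPs, with positions and minor-allele frequencies.  Used
#' as the common input of the SNP-by-SNP inbreeding estimators, the LD
#' pruner and the ROH caller.
#'
#' @param genotypes N x S integer matrix of minor-allele dosages
#'   (0/1/2; NA marks a missing genotype, which the estimators reject).
#' @param positions bp positions (0-based), strictly increasing.
#' @param p minor-allele frequencies in `(0, 0.5]`; recomputed from the
#'   genotypes when `NULL`.
#' @param derived_is_minor logical per SNP; `NA` when unknown (e.g.
#'   after reading from PED/MAP, which does not encode ancestry).
#' @param L genome length in bp (denominator of F_ROH).
#' @param c per-adjacent-bp recombination rate (used for cM in MAP
#'   output).
#' @return object of class `marker_panel`.
#' @export
marker_panel <- function(genotypes, positions, p = NULL,
                         derived_is_minor = NA, L = 1e8, c = 1e-8) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  S <- ncol(genotypes)
  stopifnot(length(positions) == S, !is.unsorted(positions, strictly = TRUE))
  if (is.null(p)) p <- colMeans(genotypes, na.rm = TRUE) / 2
  stopifnot(length(p) == S, all(p > 0), all(p <= 0.5 + 1e-12))
  if (length(derived_is_minor) == 1) derived_is_minor <- rep(derived_is_minor, S)
  structure(list(genotypes = genotypes,
                 positions = as.integer(positions),
                 p = as.numeric(p),
                 derived_is_minor = as.logical(derived_is_minor),
                 S = S, N = nrow(genotypes),
                 L = as.numeric(L), c = as.numeric(c)),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d individuals x %d SNPs, MAF in [%.4g, %.4g]\n",
              x$N, x$S, min(x$p), max(x$p)))
  invisible(x)
}

#' Extract the neutral-SNP marker panel from a population
#'
#' Takes all segregating neutral SNPs of the final generation (QTLs are
#' removed; no MAF pruning) for all individuals, and recodes genotypes
#' to minor-allele dosages using the current-generation frequencies.
#' Ties at frequency 0.5 treat the derived allele as minor.
#'
#' @param pop a `wf_population`.
#' @return a [marker_panel()].
#' @export
extract_marker_panel <- function(pop) {
  idx <- which(pop$sites$is_qtl == 0L)
  if (length(idx) == 0)
    stop("no segregating neutral SNPs in the population; replicate aborted")
  G <- genotype_dosage(pop, idx)
  qf <- colMeans(G) / 2                      # derived-allele frequency
  derived_is_minor <- qf <= 0.5
  flip <- !derived_is_minor
  if (any(flip)) G[, flip] <- 2L - G[, flip]
  marker_panel(G, pop$sites$position[idx],
               p = pmin(qf, 1 - qf),
               derived_is_minor = derived_is_minor,
               L = pop$config$L, c = pop$config$c)
}

#' Write a marker panel as PLINK PED/MAP text files
#'
#' MAP columns: chromosome (always 1), SNP id, genetic position in cM
#' (`bp * c * 100`), 1-based bp position.  PED columns: family id,
#' individual id, father, mother, sex, phenotype, then two allele
#' columns per SNP coded `1`/`2` with `2` the minor allele (`0` would be
#' missing; the simulator never produces missing genotypes).
#'
#' Note PED/MAP does not encode which allele is derived, so
#' `derived_is_minor` is not recoverable by [read_ped_map()].
#'
#' @param panel a [marker_panel()].
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return `prefix`, invisibly.
#' @export
write_ped_map <- function(panel, prefix) {
  stopifnot(inherits(panel, "marker_panel"))
  if (panel$S == 0) stop("cannot write an empty marker panel")
  if (anyNA(panel$genotypes)) stop("panel contains missing genotypes")
  map <- data.table::data.table(
    chr = 1L,
    id = paste0("snp", panel$positions + 1L),
    cm = (panel$positions + 1L) * panel$c * 100,
    bp = panel$positions + 1L
  )
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t",
                     col.names = FALSE)
  # dosage x -> allele pair: 0 -> 1 1, 1 -> 1 2, 2 -> 2 2
  a1 <- ifelse(panel$genotypes == 2L, 2L, 1L)
  a2 <- ifelse(panel$genotypes >= 1L, 2L, 1L)
  alleles <- matrix(0L, nrow = panel$N, ncol = 2L * panel$S)
  alleles[, seq(1L, 2L * panel$S, by = 2L)] <- a1
  alleles[, seq(2L, 2L * panel$S, by = 2L)] <- a2
  ped <- data.table::data.table(
    fid = paste0("fam", seq_len(panel$N)),
    iid = paste0("ind", seq_len(panel$N)),
    pat = 0L, mat = 0L, sex = 0L, phe = -9L
  )
  ped <- cbind(ped, data.table::as.data.table(alleles))
  data.table::fwrite(ped, paste0(prefix, ".ped"), sep = " ",
                     col.names = FALSE)
  invisible(prefix)
}

#' Read a marker panel from PLINK PED/MAP text files
#'
#' Dosages count the `2` (minor) allele; minor-allele frequencies are
#' recomputed from the genotypes.  The PLINK missing code `0` is
#' accepted and stored as `NA`; panels containing missing genotypes are
#' rejected by the inbreeding estimators, which assume complete data.
#'
#' @param prefix path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @param L,c genome length and recombination rate to attach to the
#'   panel (not represented in PED/MAP).
#' @return a [marker_panel()] (with `derived_is_minor = NA`).
#' @export
read_ped_map <- function(prefix, L = 1e8, c = 1e-8) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  map <- data.table::fread(map_path, header = FALSE, sep = "\t")
  if (ncol(map) != 4) stop("malformed MAP file: expected 4 columns")
  positions <- as.integer(map[[4]]) - 1L
  S <- nrow(map)
  ped <- data.table::fread(ped_path, header = FALSE, sep = " ",
                           colClasses = "character")
  if (ncol(ped) != 6 + 2 * S)
    stop(sprintf("malformed PED file: expected %d columns, found %d",
                 6 + 2 * S, ncol(ped)))
  al <- as.matrix(ped[, -(1:6)])
  bad <- !(al %in% c("0", "1", "2"))
  if (any(bad)) {
    line <- which(apply(matrix(bad, nrow = nrow(ped)), 1, any))[1]
    stop(sprintf("inconsistent allele code in PED line %d", line))
  }
  al <- matrix(as.integer(al), nrow = nrow(ped))
  a1 <- al[, seq(1L, 2L * S, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * S, by = 2L), drop = FALSE]
  x <- (a1 == 2L) + (a2 == 2L)
  x[a1 == 0L | a2 == 0L] <- NA_integer_
  # re-orient any column where allele "2" is in fact the major allele
  f2 <- colMeans(x, na.rm = TRUE) / 2
  flip <- !is.na(f2) & f2 > 0.5
  if (any(flip)) x[, flip] <- 2L - x[, flip]
  marker_panel(x, positions, p = NULL, derived_is_minor = NA, L = L, c = c)
}
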