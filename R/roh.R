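#' ROH caller parameters
#'
#' Defaults mirror the PLINK 1.9 `--homozyg` defaults: scanning windows
#' of 50 SNPs allowing 1 heterozygote (and up to 5 missing calls), a
#' per-SNP window hit-rate threshold of 0.05, a minimum of 100 SNPs per
#' segment, at least 1 SNP per 50 kb, and a maximum inter-SNP gap of
#' 1,000 kb.  Only the minimum segment length differs from PLINK's
#' default: segments are called down to `min_length_mb` (0.1 Mb by
#' default) and filtered to longer thresholds by [f_roh()].
#'
#' @param window_snp scanning window size in SNPs.
#' @param window_het maximum heterozygotes per homozygous window.
#' @param window_missing maximum missing calls per homozygous window.
#' @param window_threshold minimum fraction of homozygous windows
#'   overlapping a SNP for it to be ROH-eligible.
#' @param min_snp minimum SNPs per reported segment.
#' @param min_density_kb_per_snp maximum kb per SNP within a segment.
#' @param max_gap_kb maximum gap between consecutive segment SNPs (kb).
#' @param min_length_mb minimum segment length (Mb).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 50L, window_het = 1L,
                       window_missing = 5L, window_threshold = 0.05,
                       min_snp = 100L, min_density_kb_per_snp = 50,
                       max_gap_kb = 1000, min_length_mb = 0.1) {
  p <- list(window_snp = as.integer(window_snp),
            window_het = as.integer(window_het),
            window_missing = as.integer(window_missing),
            window_threshold = window_threshold,
            min_snp = as.integer(min_snp),
            min_density_kb_per_snp = min_density_kb_per_snp,
            max_gap_kb = max_gap_kb,
            min_length_mb = min_length_mb)
  stopifnot(all(vapply(p, function(v) v >= 0, TRUE)),
            p$min_snp >= p$window_snp)
  class(p) <- "roh_params"
  p
}

#' LD pruning of a marker panel
#'
#' Windowed pairwise pruning with PLINK `--indep-pairwise` semantics:
#' within each `window`-SNP window advanced by `step`, while any
#' retained pair of SNPs has squared dosage correlation above `r2_max`,
#' one member is removed.  Within a flagged pair the SNP with the
#' smaller minor-allele frequency is dropped; ties drop the downstream
#' SNP (the removal rule is pinned to keep pruning deterministic).
#'
#' @param panel a [marker_panel()].
#' @param window window size in SNPs.
#' @param step window increment in SNPs.
#' @param r2_max squared-correlation threshold (pairs strictly above it
#'   are pruned).
#' @return the pruned [marker_panel()].
#' @export
ld_prune <- function(panel, window = 50L, step = 5L, r2_max = 0.9) {
  stopifnot(inherits(panel, "marker_panel"), panel$S >= 2)
  if (anyNA(panel$genotypes)) stop("panel contains missing genotypes")
  x <- panel$genotypes
  storage.mode(x) <- "double"
  sds <- apply(x, 2, stats::sd)
  xs <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  keep <- ld_prune_cpp(xs, as.integer(window), as.integer(step),
                       r2_max, panel$p)
  marker_panel(panel$genotypes[, keep, drop = FALSE],
               panel$positions[keep], p = panel$p[keep],
               derived_is_minor = panel$derived_is_minor[keep],
               L = panel$L, c = panel$c)
}

#' Call runs of homozygosity for one individual
#'
#' PLINK-style scan: every contiguous window of `window_snp` SNPs with
#' at most `window_het` heterozygotes is "homozygous"; each SNP's hit
#' rate is the fraction of windows containing it that are homozygous;
#' SNPs with hit rate at least `window_threshold` are ROH-eligible.
#' Maximal runs of eligible SNPs are split at inter-SNP gaps larger
#' than `max_gap_kb`, then filtered by `min_snp`, `min_length_mb` and
#' SNP density.  A segment's span is the bp distance from its first to
#' its last SNP.  Homozygosity is label-free, so the call is invariant
#' to allele relabelling.
#'
#' @param x dosage vector (0/1/2) of one individual over the (pruned)
#'   panel SNPs; `NA` counts as a missing call.
#' @param positions bp positions of the SNPs, increasing.
#' @param params a [roh_params()].
#' @return data.frame with columns `start_bp`, `end_bp`, `n_snps`
#'   (zero rows when no segment qualifies; with a warning when there
#'   are fewer SNPs than one window).
#' @export
call_roh <- function(x, positions, params = roh_params()) {
  stopifnot(length(x) == length(positions))
  S <- length(x)
  w <- params$window_snp
  empty <- data.frame(start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0))
  if (S < w) {
    warning("fewer SNPs than one scanning window; no ROH called")
    return(empty)
  }
  het <- as.integer(x == 1L)
  mis <- as.integer(is.na(x))
  het[is.na(het)] <- 0L
  # heterozygote / missing counts of the S - w + 1 windows
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  nw <- S - w + 1L
  wh <- ch[(w + 1L):(S + 1L)] - ch[1L:nw]
  wm <- cm[(w + 1L):(S + 1L)] - cm[1L:nw]
  homw <- as.integer(wh <= params$window_het & wm <= params$window_missing)
  # hit rate of SNP j over windows starting in [j - w + 1, j]
  cw <- c(0L, cumsum(homw))
  j <- seq_len(S)
  lo <- pmax(j - w + 1L, 1L)
  hi <- pmin(j, nw)
  hits <- cw[hi + 1L] - cw[lo]
  total <- hi - lo + 1L
  eligible <- hits / total >= params$window_threshold
  if (!any(eligible)) return(empty)
  # maximal eligible runs, split at large gaps
  gap_bp <- params$max_gap_kb * 1000
  brk <- c(TRUE, diff(eligible) != 0 | (diff(positions) > gap_bp & eligible[-1]))
  grp <- cumsum(brk)
  segs <- lapply(split(which(eligible), grp[eligible]), function(idx) {
    data.frame(start_bp = positions[idx[1]],
               end_bp = positions[idx[length(idx)]],
               n_snps = length(idx))
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  len <- out$end_bp - out$start_bp
  keep <- out$n_snps >= params$min_snp &
    len >= params$min_length_mb * 1e6 &
    (len / 1000) / out$n_snps <= params$min_density_kb_per_snp
  out[keep, , drop = FALSE]
}

#' Genome fraction in ROH above a length threshold
#'
#' @param segments data.frame from [call_roh()].
#' @param min_length_mb minimum segment length in Mb to count.
#' @param genome_length genome length in bp (denominator).
#' @return F_ROH in `[0, 1]`.
#' @export
#' @examples
#' segs <- data.frame(start_bp = 0, end_bp = 2e6, n_snps = 500)
#' f_roh(segs, 1, 1e8)   # 0.02
#' f_roh(segs, 5, 1e8)   # 0
f_roh <- function(segments, min_length_mb, genome_length) {
  if (nrow(segments) == 0) return(0)
  len <- segments$end_bp - segments$start_bp
  sum(len[len >= min_length_mb * 1e6]) / genome_length
}

#' Per-individual F_ROH at several length thresholds
#'
#' Calls ROH once per individual (at the smallest threshold in
#' `params`) and evaluates [f_roh()] at each requested threshold.  The
#' denominator is the configured genome length `panel$L`, not the
#' SNP-spanned range.
#'
#' @param panel a (typically LD-pruned) [marker_panel()].
#' @param params a [roh_params()].
#' @param thresholds_mb numeric vector of minimum segment lengths (Mb).
#' @return N x length(thresholds) matrix with columns `F_ROH_<t>`.
#' @export
roh_inbreeding <- function(panel, params = roh_params(),
                           thresholds_mb = c(0.1, 1, 5)) {
  stopifnot(inherits(panel, "marker_panel"))
  out <- matrix(0, nrow = panel$N, ncol = length(thresholds_mb),
                dimnames = list(NULL, paste0("F_ROH_", thresholds_mb)))
  for (i in seq_len(panel$N)) {
    segs <- call_roh(panel$genotypes[i, ], panel$positions, params)
    for (t in seq_along(thresholds_mb)) {
      out[i, t] <- f_roh(segs, thresholds_mb[t], panel$L)
    }
  }
  out
}
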