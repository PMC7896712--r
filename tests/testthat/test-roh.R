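test_that("LD pruning removes exactly one of a perfectly correlated pair", {
  set.seed(1)
  x <- matrix(rbinom(40 * 4, 2, 0.4), 40, 4)
  x[, 3] <- x[, 2]                       # identical pair (r^2 = 1)
  f <- colMeans(x) / 2
  x[, f > 0.5] <- 2L - x[, f > 0.5]
  panel <- marker_panel(x, positions = c(100L, 200L, 300L, 400L))
  pruned <- ld_prune(panel, window = 4, step = 2)
  expect_equal(pruned$S, 3)
  # equal MAF in the pair: the downstream SNP is dropped
  expect_equal(pruned$positions, c(100L, 200L, 400L))
})

test_that("LD pruning leaves weakly correlated panels untouched", {
  set.seed(2)
  x <- matrix(rbinom(200 * 10, 2, 0.5), 200, 10)
  f <- colMeans(x) / 2
  x[, f > 0.5] <- 2L - x[, f > 0.5]
  panel <- marker_panel(x, positions = seq(100L, 1000L, by = 100L))
  r2 <- cor(x)^2
  skip_if(max(r2[upper.tri(r2)]) > 0.9)  # random draw degenerate (never seen)
  pruned <- ld_prune(panel)
  expect_equal(pruned$S, 10)
})

test_that("windowed pruning matches a brute-force oracle on a small panel", {
  # oracle: scan pairs (i, j) in the pinned order over one full window,
  # dropping the smaller-MAF member (ties: downstream) until stable
  prune_oracle <- function(x, p, r2max = 0.9) {
    S <- ncol(x)
    keep <- rep(TRUE, S)
    for (i in seq_len(S)) {
      if (!keep[i]) next
      for (j in seq_len(S)) {
        if (j <= i || !keep[j]) next
        if (!keep[i]) break
        if (cor(x[, i], x[, j])^2 > r2max) {
          drop <- if (p[i] < p[j]) i else j
          keep[drop] <- FALSE
        }
      }
    }
    keep
  }
  set.seed(33)
  n <- 60
  base <- rbinom(n, 2, 0.3)
  x <- cbind(base,
             ifelse(rbinom(n, 1, 0.02) == 1, 2 - base, base),  # ~r2 > 0.9
             rbinom(n, 2, 0.45),
             base,                                             # identical
             rbinom(n, 2, 0.2),
             rbinom(n, 2, 0.5))
  f <- colMeans(x) / 2
  x[, f > 0.5] <- 2 - x[, f > 0.5]
  colnames(x) <- NULL
  p <- colMeans(x) / 2
  panel <- marker_panel(x, positions = seq(10L, 60L, by = 10L), p = p)
  pruned <- ld_prune(panel, window = 6, step = 6)
  expect_equal(pruned$positions,
               panel$positions[prune_oracle(x, p)])
})

# direct enumeration of the window-scan rule (no cumulative-sum tricks),
# for single-run fixtures without gap/density complications
roh_oracle <- function(x, pos, w = 50, het_max = 1, thr = 0.05) {
  S <- length(x)
  nw <- S - w + 1
  homw <- vapply(seq_len(nw), function(s) {
    sum(x[s:(s + w - 1)] == 1L) <= het_max
  }, logical(1))
  elig <- vapply(seq_len(S), function(j) {
    starts <- max(1, j - w + 1):min(j, nw)
    mean(homw[starts]) >= thr
  }, logical(1))
  idx <- which(elig)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  runs <- runs[lengths(runs) >= 100]
  stopifnot(length(runs) == 1)
  r <- runs[[1]]
  list(start_bp = pos[r[1]], end_bp = pos[r[length(r)]], n_snps = length(r))
}

test_that("the ROH caller handles hand-checkable genotype vectors", {
  params <- roh_params()

  # fully homozygous individual: one segment spanning the SNP range
  S <- 2000
  pos <- as.integer(seq(0, 1e8, length.out = S))
  segs <- call_roh(rep(0L, S), pos, params)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, S)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[S])

  # heterozygote every 25 SNPs: every 50-SNP window holds >= 2 hets
  x <- rep(0L, S)
  x[seq(1, S, by = 25)] <- 1L
  expect_equal(nrow(call_roh(x, pos, params)), 0)

  # 150 homozygous SNPs spanning 2 Mb flanked by dense heterozygotes:
  # one segment covering the homozygous tract (up to window-edge SNPs),
  # checked against a plain window-enumeration oracle
  x <- rep(c(0L, 1L), length.out = 3000)   # het every other SNP
  pos <- as.integer(c(seq(0, 0.9e6, length.out = 1425),
                      seq(1e6, 3e6, length.out = 150),
                      seq(3.1e6, 4e6, length.out = 1425)))
  x[1426:1575] <- 0L
  segs <- call_roh(x, pos, params)
  oracle <- roh_oracle(x, pos)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, oracle$n_snps)
  expect_equal(c(segs$start_bp, segs$end_bp), c(oracle$start_bp, oracle$end_bp))
  # the tract interior is covered; edges may move by a few window SNPs
  expect_lt(abs(segs$n_snps - 150), 6)
  expect_lt(abs((segs$end_bp - segs$start_bp) - 2e6), 2e5)

  # fewer SNPs than one window: warning, empty result
  expect_warning(out <- call_roh(rep(0L, 10), 1:10, params), "fewer SNPs")
  expect_equal(nrow(out), 0)
})

test_that("segments split at large gaps and respect the density filter", {
  params <- roh_params()
  # 300 homozygous SNPs with a 2 Mb gap in the middle: two segments
  pos <- as.integer(c(seq(0, 1.4e6, length.out = 150),
                      seq(3.5e6, 4.9e6, length.out = 150)))
  segs <- call_roh(rep(0L, 300), pos, params)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_snps, c(150, 150))

  # too sparse: 150 SNPs over 60 Mb is 400 kb/SNP > 50 kb/SNP
  pos_sparse <- as.integer(seq(0, 6e7, length.out = 150))
  expect_equal(nrow(call_roh(rep(0L, 150), pos_sparse, params)), 0)
})

test_that("F_ROH arithmetic and threshold monotonicity hold", {
  segs <- data.frame(start_bp = 0, end_bp = 2e6, n_snps = 500)
  expect_equal(f_roh(segs, 1, 1e8), 0.02)
  expect_equal(f_roh(segs, 5, 1e8), 0)
  expect_equal(f_roh(segs[0, ], 1, 1e8), 0)
  whole <- data.frame(start_bp = c(0, 5e7), end_bp = c(5e7, 1e8),
                      n_snps = c(1e4, 1e4))
  expect_equal(f_roh(whole, 1, 1e8), 1)

  # monotone in the length threshold on simulated data
  cfg <- sim_config(N = 50, U = 6, generations = 500, seed = 21)
  panel <- ld_prune(extract_marker_panel(run_replicate(cfg)))
  fr <- roh_inbreeding(panel, roh_params(), c(0.1, 1, 5))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(all(fr[, "F_ROH_1"] <= fr[, "F_ROH_0.1"]))
  expect_true(all(fr[, "F_ROH_5"] <= fr[, "F_ROH_1"]))
})

test_that("ROH calls are invariant to allele relabelling", {
  cfg <- sim_config(N = 40, U = 3, generations = 300, seed = 31)
  panel <- ld_prune(extract_marker_panel(run_replicate(cfg)))
  x <- panel$genotypes[1, ]
  a <- call_roh(x, panel$positions)
  b <- call_roh(2L - x, panel$positions)
  expect_identical(a, b)
})
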