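# Build a wf_population by hand from a haplotype matrix and site table.
make_pop <- function(haplotypes, position, is_qtl = rep(0L, length(position)),
                     s = rep(0, length(position)), a = rep(0, length(position)),
                     h = rep(0.2, length(position)), L = 1e8, c = 1e-8,
                     config = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  N <- nrow(haplotypes) / 2
  if (is.null(config)) {
    config <- sim_config(N = max(N, 2), L = L, c = c, U = 0,
                         generations = 1, seed = 1)
  }
  structure(list(
    haplotypes = haplotypes,
    sites = data.frame(position = as.integer(position),
                       is_qtl = as.integer(is_qtl),
                       s = s, a = a, h = h,
                       origin_gen = 0L),
    generation = 1L, N = N, config = config,
    n_fixed = 0, n_lost = 0, n_fixed_qtl = 0, n_new_mutations = 0,
    dropped = NULL
  ), class = "wf_population")
}

# Random segregating marker panel (for algebraic identity checks).
random_panel <- function(N, S, seed) {
  set.seed(seed)
  repeat {
    q <- runif(S, 0.05, 0.95)
    x <- matrix(rbinom(N * S, 2, rep(q, each = N)), N, S)
    mono <- colSums(x) == 0 | colSums(x) == 2 * N
    if (!any(mono)) break
  }
  f <- colMeans(x) / 2
  flip <- f > 0.5
  x[, flip] <- 2L - x[, flip]
  marker_panel(x, positions = sort(sample.int(1e6, S)))
}
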