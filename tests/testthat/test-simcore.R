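test_that("mutation effect sampler matches its marginal distributions", {
  cfg <- sim_config(N = 100, U = 1, seed = 1)

  # forced neutrality
  set.seed(1)
  eff <- draw_mutation_effects(500, sim_config(N = 100, U = 1,
                                               prop_causal = 0, seed = 1))
  expect_true(all(eff$is_qtl == 0L))
  expect_true(all(eff$s == 0) && all(eff$a == 0))

  # causal draws: exponential marginal (beta = 1) with mean -0.03
  cfg1 <- sim_config(N = 100, U = 1, prop_causal = 1, seed = 1)
  set.seed(2)
  eff <- draw_mutation_effects(1e5, cfg1)
  expect_equal(mean(eff$s), -0.03, tolerance = 0.01)       # 3 SE ~ 2.8e-4
  expect_equal(var(eff$s), 0.0009, tolerance = 0.08)       # exponential: var = mean^2
  expect_true(all(eff$s <= 0))
  expect_true(all(eff$h == 0.2))

  # rho = 1 forces exact proportionality a = trait_scale * s
  cfg2 <- sim_config(N = 100, U = 1, prop_causal = 1, trait_scale = 2.5,
                     seed = 1)
  set.seed(3)
  eff <- draw_mutation_effects(1000, cfg2)
  expect_equal(eff$a, 2.5 * eff$s, tolerance = 1e-12)
  expect_equal(cor(eff$a, eff$s), 1)

  # rho < 1: gamma marginals preserved, Pearson correlation = rho
  cfg3 <- sim_config(N = 100, U = 1, prop_causal = 1, rho = 0.5, seed = 1)
  set.seed(4)
  eff <- draw_mutation_effects(1e5, cfg3)
  expect_equal(cor(eff$s, eff$a), 0.5, tolerance = 0.02)
  expect_equal(mean(eff$a), -0.03, tolerance = 0.01)
  expect_equal(var(eff$a), 0.0009, tolerance = 0.08)
})

test_that("variable dominance is inversely tied to |s| with the right mean", {
  k <- variable_dominance_k(-0.03, beta = 1, h_target = 0.2)
  expect_equal(k, 50)  # closed form: ((2*0.2)^(-1) - 1) / 0.03

  # independent oracle: E[h] = 0.5 * E[exp(-k|s|)] over the gamma density
  for (beta in c(0.5, 1, 2)) {
    k <- variable_dominance_k(-0.03, beta = beta, h_target = 0.2)
    eh <- stats::integrate(function(x) {
      0.5 * exp(-k * x) * stats::dgamma(x, shape = beta, scale = 0.03 / beta)
    }, 0, Inf)$value
    expect_equal(eh, 0.2, tolerance = 1e-4)
  }

  # empirical mean dominance over sampled mutations
  cfg <- sim_config(N = 100, U = 1, prop_causal = 1,
                    h_model = "variable_CK", seed = 1)
  set.seed(5)
  eff <- draw_mutation_effects(1e5, cfg)
  expect_equal(mean(eff$h), 0.2, tolerance = 0.01)
  # h -> 0 for strongly selected mutations
  expect_lt(mean(eff$h[abs(eff$s) > 0.1]), 0.05)
  expect_true(all(eff$h >= 0 & eff$h <= 1))
})

test_that("gamete formation recombines at ~1 Morgan and respects parents", {
  S <- 40
  pos <- sort(sample.int(1e8, S))
  hapA <- rep(0L, S)
  hapB <- rep(1L, S)

  # no recombination: gamete is one parental strand
  set.seed(1)
  g <- make_gamete(hapA, hapB, pos, L = 1e8, c = 0)
  expect_equal(g$n_crossovers, 0)
  expect_true(all(g$gamete == 0L) || all(g$gamete == 1L))

  # homozygous parent: gamete equals either strand regardless of crossovers
  set.seed(2)
  g <- make_gamete(hapB, hapB, pos, L = 1e8, c = 1e-7)
  expect_equal(g$gamete, hapB)

  # both strands are used with ~equal probability
  set.seed(3)
  picks <- replicate(400, make_gamete(hapA, hapB, pos, 1e8, 0)$gamete[1])
  expect_gt(mean(picks), 0.35)
  expect_lt(mean(picks), 0.65)

  # crossover count ~ Poisson(c*(L-1)): mean 1 at c = 1e-8, L = 1e8
  set.seed(4)
  k <- replicate(2e4, make_gamete(hapA, hapB, pos, 1e8, 1e-8)$n_crossovers)
  expect_equal(mean(k), 1, tolerance = 3 * sqrt(1 / 2e4))

  # with crossovers the gamete alternates strands in position order
  set.seed(5)
  repeat {
    g <- make_gamete(hapA, hapB, pos, 1e8, 5e-8)
    if (g$n_crossovers >= 1) break
  }
  expect_lte(length(rle(g$gamete)$lengths), g$n_crossovers + 1)
})

test_that("fitness is multiplicative and phenotype additive over QTLs", {
  # hand-evaluated single-locus cases
  expect_equal(fitness_multiplicative(matrix(0, 1, 1), -0.1, 0.2), 1)
  expect_equal(fitness_multiplicative(matrix(1, 1, 1), -0.1, 0.2), 0.98)
  expect_equal(fitness_multiplicative(matrix(2, 1, 1), -0.1, 0.2), 0.9)
  expect_equal(fitness_multiplicative(matrix(c(2, 2), 1, 2),
                                      c(-0.1, -0.1), c(0.2, 0.2)), 0.81)
  expect_equal(fitness_multiplicative(matrix(0L, 3, 0), numeric(0),
                                      numeric(0)), rep(1, 3))

  expect_equal(phenotype_additive(matrix(0, 1, 1), -1, 0.2), 0)
  expect_equal(phenotype_additive(matrix(1, 1, 1), -1, 0.2), -0.2)
  expect_equal(phenotype_additive(matrix(2, 1, 1), -1, 0.2), -1)
  expect_equal(phenotype_additive(matrix(c(1, 2), 1, 2), c(-1, -0.5),
                                  c(0.2, 0.2)), -0.7)
})

test_that("run_replicate is deterministic and keeps sites segregating", {
  cfg <- sim_config(N = 30, U = 1, generations = 120, seed = 99)
  pop1 <- run_replicate(cfg)
  pop2 <- run_replicate(cfg)
  expect_identical(pop1$haplotypes, pop2$haplotypes)
  expect_identical(pop1$sites, pop2$sites)

  # all indexed sites strictly segregating, sorted by position
  cnt <- colSums(pop1$haplotypes)
  expect_true(all(cnt > 0 & cnt < 2 * cfg$N))
  expect_false(is.unsorted(pop1$sites$position, strictly = TRUE))

  # zero generations: the founding population is devoid of variation
  pop0 <- run_replicate(sim_config(N = 30, U = 1, generations = 0, seed = 1))
  expect_equal(nrow(pop0$sites), 0)
  expect_equal(dim(pop0$haplotypes), c(60, 0))
})

test_that("neutral one-generation drift matches the binomial oracle", {
  # one site at p = 0.5; offspring frequency variance must be p(1-p)/2N
  N <- 100
  freqs <- freq_change_trials()
  n_trials <- length(freqs)
  expect_equal(mean(freqs) - 0.5, 0, tolerance = 3 * sqrt(0.00125 / n_trials))
  oracle <- 0.5 * 0.5 / (2 * N)                      # binomial sampling
  expect_equal(var(freqs), oracle, tolerance = 0.1)
})

test_that("selection weights parents by fitness", {
  # one lethal recessive QTL fixed in all but one individual: the only
  # parent with positive fitness is selfed by everyone
  N <- 10
  hap <- matrix(1L, nrow = 2 * N, ncol = 1)
  hap[1:2, 1] <- 0L
  pop <- make_pop(hap, position = 5L, is_qtl = 1L, s = -1, a = -1, h = 0,
                  config = sim_config(N = N, U = 0, c = 0,
                                      generations = 1, seed = 1))
  nxt <- run_replicate(pop$config, init = pop, generations = 1, seed = 3)
  # the surviving parent is 0/0, so every offspring is 0/0 and the QTL is lost
  expect_equal(nrow(nxt$sites), 0)
  expect_equal(nxt$n_lost, 1)

  # degenerate case: everyone homozygous for the lethal -> abort
  hap_all <- matrix(1L, nrow = 2 * N, ncol = 1)
  pop_bad <- make_pop(hap_all, position = 5L, is_qtl = 1L, s = -1, a = -1,
                      h = 0,
                      config = sim_config(N = N, U = 0, c = 0,
                                          generations = 1, seed = 1))
  expect_error(run_replicate(pop_bad$config, init = pop_bad, generations = 1),
               "zero fitness")
})

test_that("Watterson initialisation matches the harmonic-sum oracle", {
  # oracle: U = S / (4 N sum_{i<2N} 1/i)
  expect_equal(watterson_mutation_rate(100, 30000),
               30000 / (400 * sum(1 / 1:199)))
  expect_equal(watterson_mutation_rate(100, 30000), 12.8, tolerance = 0.01)
})
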