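# Memoised expensive computations shared across test files; each is
# computed at most once per test run.
.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .test_cache)
  }
  get(name, envir = .test_cache, inherits = FALSE)
}

# Default study conditions at N = 100 (calibrated U and trait scale),
# analyzed over 30 seeded replicates.
default_scenario <- function() {
  cached("default_scenario", {
    cfg <- sim_config(N = 100, seed = 20260901L)
    cfg <- calibrate_rates(cfg, n_pilot = 2L)
    run_scenario(cfg, 30L)
  })
}

# Neutral replicates (no QTLs) used for the drift-limit checks; smaller
# marker panels keep them cheap without touching the neutral dynamics.
neutral_runs <- function() {
  cached("neutral_runs", {
    cfg <- sim_config(N = 100, U = 1.5, prop_causal = 0,
                      generations = 300L, seed = 20260902L)
    set.seed(cfg$seed)
    seeds <- sample.int(.Machine$integer.max, 60L)
    lapply(seeds, function(s) run_replicate(cfg, seed = s))
  })
}

# One-generation neutral resampling trials of a p = 0.5 site at N = 100.
freq_change_trials <- function() {
  cached("freq_change_trials", {
    N <- 100
    hap <- matrix(rep(c(1L, 0L), N), ncol = 1)
    cfg <- sim_config(N = N, U = 0, c = 0, prop_causal = 0,
                      generations = 1, seed = 1)
    pop <- make_pop(hap, position = 1000L, config = cfg)
    vapply(seq_len(3000), function(i) {
      nxt <- run_replicate(cfg, init = pop, generations = 1, seed = i,
                           track_dropped_from = 0L)
      if (nrow(nxt$sites) == 1) mean(nxt$haplotypes) else
        ifelse(nxt$dropped$fate[1] == "fixed", 1, 0)
    }, numeric(1))
  })
}

# Neutral drift continued 50 generations past a reference snapshot, with
# the dropped-site log enabled so snapshot genotypes can be rebuilt.
drift_runs <- function() {
  cached("drift_runs", {
    cfg <- sim_config(N = 100, U = 1.5, prop_causal = 0,
                      generations = 300L, seed = 20260903L)
    set.seed(cfg$seed)
    seeds <- sample.int(.Machine$integer.max - 1L, 30L)
    lapply(seeds, function(s) {
      pop0 <- run_replicate(cfg, seed = s)
      neutral <- which(pop0$sites$is_qtl == 0L)
      q0 <- colMeans(genotype_dosage(pop0, neutral)) / 2
      pos0 <- pop0$sites$position[neutral]
      pop1 <- run_replicate(cfg, init = pop0, generations = 50L,
                            seed = s + 1L,
                            track_dropped_from = pop0$generation)
      list(pos0 = pos0, q0 = q0, pop1 = pop1)
    })
  })
}
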