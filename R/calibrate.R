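#' Calibrate the mutation rate and trait scale
#'
#' Tunes the two free rates of a configuration to the study conditions:
#' the haploid-genome mutation rate `U` so that the final generation
#' segregates about `snp_target` neutral SNPs, and the trait-effect
#' multiplier `trait_scale` so that the realized inbreeding load (sum of
#' `2dpq` over segregating QTLs) is about `config$id_target`.
#'
#' `U` is initialized from the neutral Watterson expectation
#' (`E[S] = 4NU * sum 1/i`, see [watterson_mutation_rate()]) and refined
#' by full-length pilot replicates: the observed neutral SNP count
#' rescales `U` linearly.  Trait effects do not influence the allele
#' dynamics (selection acts through `s` only), so the realized load
#' scales exactly linearly in `trait_scale` and, to first order, in `U`
#' (the number of segregating QTLs); one pilot round therefore fixes
#' both rates.  Additional rounds re-observe with the refined rates.
#'
#' @param config a [sim_config()].
#' @param snp_target target neutral segregating-SNP count.
#' @param n_pilot pilot replicates per round.
#' @param n_rounds refinement rounds.
#' @param seeds optional pilot seeds (length `n_pilot * n_rounds`);
#'   derived from `config$seed` when `NULL`.
#' @return The calibrated `sim_config`, with attribute `"calibration"`
#'   holding the pilot observations.  Warns when the last observed
#'   neutral SNP count is more than 25% away from the target.
#' @export
calibrate_rates <- function(config, snp_target = config$snp_target,
                            n_pilot = 2L, n_rounds = 1L, seeds = NULL) {
  stopifnot(inherits(config, "sim_config"), n_pilot >= 1, n_rounds >= 1)
  if (is.null(seeds)) {
    set.seed(config$seed + 1L)
    seeds <- sample.int(.Machine$integer.max, n_pilot * n_rounds)
  }
  stopifnot(length(seeds) >= n_pilot * n_rounds)
  if (config$id_target == 0) {
    config$trait_scale <- 0
    return(config)
  }
  log <- list()
  for (round in seq_len(n_rounds)) {
    s_obs <- numeric(n_pilot)
    b_obs <- numeric(n_pilot)
    for (k in seq_len(n_pilot)) {
      pop <- run_replicate(config, seed = seeds[(round - 1) * n_pilot + k])
      s_obs[k] <- sum(pop$sites$is_qtl == 0L)
      b_obs[k] <- true_id_2dpq(pop)
    }
    u_old <- config$U
    config$U <- config$U * snp_target / mean(s_obs)
    # realized load scales linearly in trait_scale and ~linearly in U
    b_adj <- mean(b_obs) * config$U / u_old
    config$trait_scale <- config$trait_scale * config$id_target / b_adj
    log[[round]] <- list(U = u_old, neutral_snps = s_obs, B = b_obs)
  }
  last_s <- mean(log[[n_rounds]]$neutral_snps)
  if (abs(last_s - snp_target) / snp_target > 0.25) {
    warning(sprintf(
      "pilot neutral SNP count (%.0f) is far from the target (%d); reporting best rates",
      last_s, snp_target))
  }
  attr(config, "calibration") <- log
  config
}
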