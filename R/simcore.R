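#' Run one forward-time replicate
#'
#' Simulates `config$generations` discrete generations of a diploid
#' monoecious Wright-Fisher population of constant size `N` with random
#' mating (two fitness-proportional parent draws with replacement, so
#' selfing is possible), Poisson recombination without interference,
#' infinite-sites mutation on discrete bp positions, and multiplicative
#' purifying selection on pleiotropic QTLs.  Sites fixed or lost are
#' compacted out of the state after every generation (counts are
#' retained; fixed trait effects shift the population mean uniformly and
#' cannot affect regressions on F).
#'
#' The run is deterministic given `config$seed` (or `seed`).
#'
#' @param config a [sim_config()] object.
#' @param init optional `wf_population` to continue from (e.g. to record
#'   reference-generation allele frequencies and then advance further
#'   generations); the founding population is otherwise devoid of
#'   variation.
#' @param generations number of generations to run; defaults to
#'   `config$generations`.
#' @param seed RNG seed; defaults to `config$seed`.
#' @param track_dropped_from if non-negative, fixed/lost sites from this
#'   generation onwards are logged in the `dropped` table (position,
#'   fate, generation), allowing genotypes at a past marker snapshot to
#'   be reconstructed with [genotypes_at()].
#'
#' @return An object of class `wf_population`: a list with elements
#'   `haplotypes` (2N x S 0/1 integer matrix, derived-allele coding,
#'   sites sorted by position), `sites` (data.frame with `position`
#'   (0-based bp), `is_qtl`, `s`, `a`, `h`, `origin_gen`), `generation`,
#'   `N`, `config`, drop counters and (optionally) the `dropped` log.
#' @export
#' @examples
#' cfg <- sim_config(N = 20, generations = 40, U = 1, seed = 42)
#' pop <- run_replicate(cfg)
#' pop
run_replicate <- function(config, init = NULL, generations = NULL,
                          seed = NULL, track_dropped_from = -1L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(generations)) generations <- config$generations
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  ep <- .effect_params(config)
  if (is.null(init)) {
    hap0 <- matrix(0L, nrow = 2L * config$N, ncol = 0L)
    pos0 <- integer(0); isq0 <- integer(0); or0 <- integer(0)
    s0 <- numeric(0); a0 <- numeric(0); h0 <- numeric(0)
    start_gen <- 0L
  } else {
    stopifnot(inherits(init, "wf_population"), init$N == config$N)
    hap0 <- init$haplotypes
    pos0 <- init$sites$position
    isq0 <- init$sites$is_qtl
    s0 <- init$sites$s; a0 <- init$sites$a; h0 <- init$sites$h
    or0 <- init$sites$origin_gen
    start_gen <- init$generation
  }
  res <- sim_run_cpp(config$N, config$L, config$c, config$U,
                     as.integer(generations), ep, hap0,
                     as.integer(pos0), as.integer(isq0),
                     as.numeric(s0), as.numeric(a0), as.numeric(h0),
                     as.integer(or0), as.integer(start_gen),
                     as.integer(track_dropped_from))
  sites <- data.frame(
    position = res$position, is_qtl = res$is_qtl,
    s = res$s, a = res$a, h = res$h, origin_gen = res$origin_gen
  )
  dropped <- if (track_dropped_from >= 0) {
    data.frame(position = res$dropped_pos,
               fate = ifelse(res$dropped_fixed == 1, "fixed", "lost"),
               generation = res$dropped_gen,
               is_qtl = res$dropped_is_qtl)
  } else NULL
  structure(list(
    haplotypes = res$haplotypes,
    sites = sites,
    generation = res$generation,
    N = config$N,
    config = config,
    n_fixed = res$n_fixed, n_lost = res$n_lost,
    n_fixed_qtl = res$n_fixed_qtl,
    n_new_mutations = res$n_new_mutations,
    dropped = dropped
  ), class = "wf_population")
}

#' @export
print.wf_population <- function(x, ...) {
  nq <- sum(x$sites$is_qtl)
  cat(sprintf(
    "wf_population: N = %d, generation %d, %d segregating sites (%d neutral, %d QTL)\n",
    x$N, x$generation, nrow(x$sites), nrow(x$sites) - nq, nq))
  cat(sprintf("  fixed since founding: %d (%d QTL), lost: %d\n",
              x$n_fixed, x$n_fixed_qtl, x$n_lost))
  invisible(x)
}

#' Draw mutation records
#'
#' Samples `n` new-mutation records under a configuration: neutral with
#' probability `1 - prop_causal` (`s = a = 0`), otherwise pleiotropic
#' with `|s|` and `|a|` gamma-distributed (mean `|mean_s|`, shape
#' `beta`; `a` additionally multiplied by `trait_scale`) and Pearson
#' correlation `rho` between `|a|` and `|s|`, and dominance per the
#' configured model.  Uses the current RNG state.
#'
#' @param n number of records.
#' @param config a [sim_config()].
#' @return data.frame with columns `is_qtl`, `s`, `a`, `h`.
#' @export
draw_mutation_effects <- function(n, config) {
  stopifnot(inherits(config, "sim_config"), n >= 0)
  draw_effects_cpp(as.integer(n), .effect_params(config))
}

#' Form a single gamete (recombination only)
#'
#' Test/inspection surface for the gamete-formation step: applies a
#' Poisson(`c * (L - 1)`) number of crossovers at uniform positions (no
#' interference) to one parental haplotype pair, starting from a
#' fair-coin strand choice.  New mutations are not added here.
#'
#' @param hapA,hapB parental haplotypes (0/1 vectors over the same
#'   sites).
#' @param positions site positions in bp, strictly increasing.
#' @param L genome length in bp.
#' @param c per-adjacent-bp recombination rate (Morgans).
#' @return list with `gamete` and `n_crossovers`.
#' @export
make_gamete <- function(hapA, hapB, positions, L, c) {
  sim_gamete_cpp(as.integer(hapA), as.integer(hapB),
                 as.integer(positions), L, c)
}

#' Genotype dosage matrix of a population
#'
#' @param pop a `wf_population`.
#' @param sites optional column index of sites to extract.
#' @return N x S integer matrix of derived-allele dosages (0/1/2).
#' @export
genotype_dosage <- function(pop, sites = NULL) {
  H <- pop$haplotypes
  odd <- seq(1L, nrow(H), by = 2L)
  G <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  if (!is.null(sites)) G <- G[, sites, drop = FALSE]
  G
}

#' QTL genotypes and effects
#'
#' @param pop a `wf_population`.
#' @return list with `geno` (N x Q derived dosage), `s`, `a`, `h`,
#'   `position` for the segregating QTLs.
#' @export
qtl_genotypes <- function(pop) {
  idx <- which(pop$sites$is_qtl == 1L)
  list(geno = genotype_dosage(pop, idx),
       s = pop$sites$s[idx], a = pop$sites$a[idx],
       h = pop$sites$h[idx], position = pop$sites$position[idx])
}

#' Multiplicative fitness of genotypes
#'
#' Fitness is the product over QTLs of 1 (wild-type homozygote),
#' `1 + s h` (heterozygote) or `1 + s` (mutant homozygote), floored at
#' zero.
#'
#' @param geno N x Q derived dosage matrix (0/1/2).
#' @param s,h per-QTL homozygous fitness effects and dominance
#'   coefficients.
#' @return numeric vector of N fitness values.
#' @export
#' @examples
#' fitness_multiplicative(matrix(1, 1, 1), s = -0.1, h = 0.2)  # 0.98
fitness_multiplicative <- function(geno, s, h) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == length(s), length(s) == length(h))
  if (ncol(geno) == 0) return(rep(1, nrow(geno)))
  lw <- (geno == 1L) %*% cbind(log(pmax(1 + s * h, 0))) +
        (geno == 2L) %*% cbind(log(pmax(1 + s, 0)))
  pmax(as.vector(exp(lw)), 0)
}

#' Additive trait values of genotypes
#'
#' Phenotype is the sum over QTLs of 0 / `a h` / `a` by genotype; no
#' environmental noise is added.
#'
#' @param geno N x Q derived dosage matrix (0/1/2).
#' @param a,h per-QTL homozygous trait effects and dominance
#'   coefficients.
#' @return numeric vector of N trait values.
#' @export
phenotype_additive <- function(geno, a, h) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == length(a), length(a) == length(h))
  if (ncol(geno) == 0) return(rep(0, nrow(geno)))
  as.vector((geno == 1L) %*% cbind(a * h) + (geno == 2L) %*% cbind(a))
}

#' Phenotypes of a population
#'
#' @param pop a `wf_population`.
#' @return numeric vector of N phenotypic values (genotypic values of
#'   the quantitative trait; no environmental error).
#' @export
phenotypes <- function(pop) {
  q <- qtl_genotypes(pop)
  phenotype_additive(q$geno, q$a, q$h)
}

#' Reconstruct genotypes at a past marker snapshot
#'
#' Given a population run with `track_dropped_from` enabled, returns the
#' derived-allele dosages of the current individuals at an arbitrary set
#' of positions that were segregating at some earlier generation: sites
#' still segregating are read from the haplotypes, sites lost since are
#' all-0, and sites fixed since are all-2.
#'
#' @param pop a `wf_population` with a `dropped` log.
#' @param positions bp positions (0-based) of the snapshot sites.
#' @return N x length(positions) derived dosage matrix.
#' @export
genotypes_at <- function(pop, positions) {
  G <- matrix(0L, nrow = pop$N, ncol = length(positions))
  cur <- match(positions, pop$sites$position)
  seg <- !is.na(cur)
  if (any(seg)) G[, seg] <- genotype_dosage(pop, cur[seg])
  if (!all(seg)) {
    if (is.null(pop$dropped))
      stop("population has no dropped-site log; rerun with track_dropped_from")
    dr <- match(positions[!seg], pop$dropped$position)
    if (anyNA(dr)) stop("some positions are neither segregating nor logged")
    fixed <- pop$dropped$fate[dr] == "fixed"
    G[, which(!seg)[fixed]] <- 2L
  }
  G
}
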