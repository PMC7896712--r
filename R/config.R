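#' Simulation configuration
#'
#' Builds and validates the parameter set for one forward-time
#' Wright-Fisher replicate.  Defaults describe the reference study
#' conditions: a 100 Mb genome with per-adjacent-bp recombination rate
#' `c = 1e-8` (1 cM/Mb, i.e. a 1 Morgan genetic map), 5% of mutations
#' pleiotropic QTLs with gamma-distributed homozygous effects of mean
#' `-0.03` and shape `beta = 1` on fitness, perfectly correlated
#' (`rho = 1`) effects on the quantitative trait, partial recessivity
#' `h = 0.2`, and a run length of `10 N` generations (`5 N` when
#' `N >= 10000`).
#'
#' @param N population size (diploid individuals), `>= 2`.
#' @param L genome length in bp.
#' @param c recombination rate between adjacent bp, in Morgans.
#' @param U haploid genome mutation rate per generation.  The default is
#'   a Watterson-based initial value targeting `snp_target` segregating
#'   SNPs in the final generation; refine it with [calibrate_rates()].
#' @param prop_causal fraction of new mutations that are QTLs.
#' @param mean_s mean homozygous fitness effect of QTL mutations
#'   (negative).
#' @param beta gamma shape parameter of the effect-size distributions.
#' @param h dominance coefficient used when `h_model = "constant"`.
#' @param h_model `"constant"` or `"variable_CK"`.  Under
#'   `"variable_CK"` each QTL draws `h ~ U[0, exp(-k|s|)]` with `k`
#'   solved so that `E[h]` equals `h` (see [variable_dominance_k()]).
#' @param rho Pearson correlation between `|a|` and `|s|` for QTLs, in
#'   `(0, 1]`.
#' @param trait_scale multiplier applied to trait effects `a`; calibrated
#'   by [calibrate_rates()] so that the realized inbreeding load matches
#'   `id_target`.
#' @param id_target desired true rate of inbreeding depression (trait
#'   decline per unit F), used by [calibrate_rates()].
#' @param generations number of discrete generations to simulate;
#'   default `10 N` (`5 N` for `N >= 10000`).
#' @param snp_target segregating-SNP count the default `U` aims for.
#' @param seed integer RNG seed for [run_replicate()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [scenario_config()] for the named variant scenarios,
#'   [calibrate_rates()], [run_replicate()].
#' @export
#' @examples
#' cfg <- sim_config(N = 100, generations = 50, U = 2, seed = 1)
#' cfg$generations
sim_config <- function(N,
                       L = 1e8,
                       c = 1e-8,
                       U = NULL,
                       prop_causal = 0.05,
                       mean_s = -0.03,
                       beta = 1,
                       h = 0.2,
                       h_model = c("constant", "variable_CK"),
                       rho = 1,
                       trait_scale = 1,
                       id_target = 1,
                       generations = NULL,
                       snp_target = 30000,
                       seed = 1L) {
  h_model <- match.arg(h_model)
  stopifnot(
    length(N) == 1, N >= 2, N == as.integer(N),
    L >= 2, c >= 0,
    prop_causal >= 0, prop_causal <= 1,
    mean_s < 0, beta > 0,
    rho > 0, rho <= 1,
    h >= 0, h <= 0.5,
    trait_scale >= 0, id_target >= 0
  )
  if (is.null(generations)) {
    generations <- if (N >= 10000) 5L * as.integer(N) else 10L * as.integer(N)
  }
  stopifnot(generations >= 0)
  if (is.null(U)) U <- watterson_mutation_rate(N, snp_target)
  stopifnot(U >= 0)
  cfg <- list(
    N = as.integer(N), L = as.numeric(L), c = as.numeric(c),
    U = as.numeric(U),
    prop_causal = prop_causal, mean_s = mean_s, beta = beta,
    h = h, h_model = h_model, rho = rho,
    trait_scale = trait_scale, id_target = id_target,
    generations = as.integer(generations),
    snp_target = snp_target,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Wright-Fisher simulation config\n")
  cat(sprintf("  N = %d, generations = %d, genome %.3g bp, c = %.3g M/bp\n",
              x$N, x$generations, x$L, x$c))
  cat(sprintf("  U = %.4g / haploid genome, prop_causal = %.3g\n",
              x$U, x$prop_causal))
  cat(sprintf("  effects: mean_s = %.3g, beta = %.3g, rho = %.3g, h_model = %s (h = %.3g)\n",
              x$mean_s, x$beta, x$rho, x$h_model, x$h))
  cat(sprintf("  trait_scale = %.4g (id_target = %.3g), seed = %d\n",
              x$trait_scale, x$id_target, x$seed))
  invisible(x)
}

#' Watterson-based initial mutation rate
#'
#' Initial haploid-genome mutation rate `U` such that the neutral
#' equilibrium expectation of the segregating-site count in a sample of
#' `2N` sequences, `E[S] = 4 N U * sum_{i=1}^{2N-1} 1/i`, equals
#' `snp_target`.
#'
#' @param N diploid population size.
#' @param snp_target desired segregating-SNP count.
#' @return Mutation rate per haploid genome and generation.
#' @export
#' @examples
#' watterson_mutation_rate(100, 30000)  # ~12.8
watterson_mutation_rate <- function(N, snp_target = 30000) {
  a <- sum(1 / seq_len(2 * N - 1))
  snp_target / (4 * N * a)
}

#' Named variant scenarios
#'
#' Returns a [sim_config()] for one of the named variant scenarios
#' explored around the default parameter set: higher/lower recombination,
#' quarter SNP density, 10% causal mutations, stronger selection,
#' alternative gamma shapes, full recessivity, or a relaxed trait-fitness
#' correlation.
#'
#' @param name one of `"default"`, `"c_high"`, `"c_low"`,
#'   `"quarter_density"`, `"pc10"`, `"s01"`, `"beta01"`, `"beta2"`,
#'   `"h0"`, `"rho05"`.
#' @param N population size.
#' @param ... further arguments passed to [sim_config()].
#' @return A `sim_config` object.
#' @export
#' @examples
#' scenario_config("s01", N = 100, generations = 10)$mean_s
scenario_config <- function(name = c("default", "c_high", "c_low",
                                     "quarter_density", "pc10", "s01",
                                     "beta01", "beta2", "h0", "rho05"),
                            N, ...) {
  name <- match.arg(name)
  args <- switch(name,
    default = list(),
    c_high = list(c = 1e-7),
    c_low = list(c = 1e-9),
    quarter_density = list(snp_target = 7500),
    pc10 = list(prop_causal = 0.10),
    s01 = list(mean_s = -0.1),
    beta01 = list(beta = 0.1),
    beta2 = list(beta = 2),
    h0 = list(h = 0),
    rho05 = list(rho = 0.5)
  )
  do.call(sim_config, c(list(N = N), args, list(...)))
}

#' Variable-dominance rate constant
#'
#' Under the variable-dominance model each mutation draws its dominance
#' coefficient `h ~ Uniform[0, exp(-k |s|)]`, so dominance is inversely
#' related to the selection coefficient.  With `|s| ~ Gamma(beta,
#' scale = |mean_s|/beta)`, `E[h] = 0.5 (1 + k |mean_s|/beta)^(-beta)`;
#' this function returns the `k` for which `E[h] = h_target`.
#'
#' @param mean_s mean homozygous fitness effect (negative).
#' @param beta gamma shape parameter.
#' @param h_target desired mean dominance coefficient.
#' @return The rate constant `k > 0`.
#' @export
#' @examples
#' variable_dominance_k(-0.03, 1)  # 50
variable_dominance_k <- function(mean_s, beta = 1, h_target = 0.2) {
  stopifnot(mean_s < 0, beta > 0, h_target > 0, h_target < 0.5)
  theta <- -mean_s / beta
  ((2 * h_target)^(-1 / beta) - 1) / theta
}

# Gauss-Hermite nodes/weights (Golub-Welsch on the Jacobi matrix).
.gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Gaussian-copula correlation that yields Pearson correlation `rho`
# between two Gamma(beta, scale) marginals; solved by quadrature.
.copula_corr <- function(rho, beta) {
  if (rho >= 1) return(1)
  gh <- .gauss_hermite(64L)
  z <- sqrt(2) * gh$nodes
  w <- gh$weights / sqrt(pi)
  # upper-tail form keeps qgamma finite at the extreme quadrature nodes
  qfun <- function(zz) {
    stats::qgamma(stats::pnorm(zz, lower.tail = FALSE), shape = beta,
                  scale = 1, lower.tail = FALSE)
  }
  q <- qfun(z)
  m <- sum(w * q)
  v <- sum(w * q^2) - m^2
  cross <- function(r) {
    # E[q(Z1) q(r Z1 + sqrt(1-r^2) Z2)] on the tensor grid
    qq <- qfun(outer(r * z, sqrt(1 - r^2) * z, `+`))
    sum((w * q) * (qq %*% w))
  }
  f <- function(r) (cross(r) - m^2) / v - rho
  uniroot(f, c(1e-6, 1 - 1e-9), tol = 1e-9)$root
}

# Effect-sampler parameter list handed to the C++ core.
.effect_params <- function(config) {
  list(
    prop_causal = config$prop_causal,
    mean_s = config$mean_s,
    beta = config$beta,
    rho = config$rho,
    copula_r = .copula_corr(config$rho, config$beta),
    trait_scale = config$trait_scale,
    h_const = config$h,
    h_variable = identical(config$h_model, "variable_CK"),
    k_ck = if (identical(config$h_model, "variable_CK")) {
      variable_dominance_k(config$mean_s, config$beta, config$h)
    } else 0
  )
}
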