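#' Estimate the rate of inbreeding depression by regression
#'
#' The rate of inbreeding depression is estimated as minus the slope of
#' the ordinary least-squares regression (with intercept) of individual
#' phenotypic values on an inbreeding measure, so that a decline of the
#' mean with increasing F yields a positive estimate, matching the sign
#' of the true inbreeding load.
#'
#' @param phe phenotypic values (length N).
#' @param f per-individual inbreeding measure (length N).
#' @return The estimated ID (`-slope`); `NA` with a warning when `f`
#'   has zero variance.
#' @export
#' @examples
#' f <- runif(20); estimate_id(5 - 2 * f, f)  # 2
estimate_id <- function(phe, f) {
  stopifnot(length(phe) == length(f))
  v <- var(f)
  if (!is.finite(v) || v == 0) {
    warning("inbreeding measure has zero variance; ID estimate undefined")
    return(NA_real_)
  }
  -cov(phe, f) / v
}

#' Full per-replicate analysis
#'
#' Runs the complete measurement chain on a final-generation population:
#' neutral marker panel extraction, the four SNP-by-SNP inbreeding
#' estimators, LD pruning and ROH-based estimators at the requested
#' length thresholds, phenotypes, homozygous mutation loads, the true
#' inbreeding load, per-estimator ID estimates with proportional
#' deviations `(EstID - TrueID)/TrueID`, and the Pearson correlation
#' matrix of all per-individual quantities.
#'
#' @param pop a `wf_population`.
#' @param roh a [roh_params()].
#' @param thresholds_mb F_ROH length thresholds (Mb).
#' @param ld_window,ld_step,ld_r2 LD-pruning parameters.
#' @return object of class `replicate_result`: list with `true_id`,
#'   `true_id_forced`, `est_id`, `deviation`, `f_table` (per-individual
#'   estimates), `hml`, `phe`, `corr`, and panel bookkeeping (`n_snp`,
#'   `n_snp_pruned`, `n_qtl`).
#' @export
analyze_replicate <- function(pop, roh = roh_params(),
                              thresholds_mb = c(0.1, 1, 5),
                              ld_window = 50L, ld_step = 5L, ld_r2 = 0.9) {
  panel <- extract_marker_panel(pop)
  fe <- f_estimates(panel)
  pruned <- ld_prune(panel, window = ld_window, step = ld_step,
                     r2_max = ld_r2)
  froh <- roh_inbreeding(pruned, roh, thresholds_mb)
  f_table <- cbind(fe, as.data.frame(froh))
  qtl <- qtl_genotypes(pop)
  phe <- phenotype_additive(qtl$geno, qtl$a, qtl$h)
  hml <- hml_counts(panel, qtl)
  B <- true_id_2dpq(pop)
  est <- vapply(f_table, function(f) estimate_id(phe, f), numeric(1))
  dev <- if (B > 0) (est - B) / B else rep(NA_real_, length(est))
  names(dev) <- names(est)
  corr <- cor(cbind(f_table, Phe = phe, hml))
  structure(list(
    true_id = B,
    true_id_forced = true_id_forced_homozygosity(pop),
    est_id = est, deviation = dev,
    f_table = f_table, hml = hml, phe = phe, corr = corr,
    n_snp = panel$S, n_snp_pruned = pruned$S, n_qtl = ncol(qtl$geno)
  ), class = "replicate_result")
}

#' Aggregate replicate results into a scenario summary
#'
#' Cross-replicate summaries of the evaluation: mean and
#' across-individual variance of every F measure, mean proportional
#' deviation of each ID estimate with its empirical central 95% interval
#' (2.5% of the extreme deviations excluded at each side), the RMSE of
#' the proportional deviations with a nonparametric bootstrap standard
#' error, and the averaged correlation matrix with standard errors.
#'
#' @param results list of [analyze_replicate()] outputs.
#' @param n_boot bootstrap resamples for the RMSE standard error.
#' @return object of class `scenario_summary`: list with `n_replicates`,
#'   `f_mean`, `f_mean_se`, `f_var`, `f_var_se`, `true_id_mean`,
#'   `deviation` (data.frame: mean, se, q2.5, q97.5, rmse, rmse_se per
#'   estimator), `corr_mean`, `corr_se`.
#' @export
aggregate_replicates <- function(results, n_boot = 1000L) {
  stopifnot(length(results) >= 1)
  est_names <- names(results[[1]]$est_id)
  R <- length(results)
  per_rep <- function(fn) {
    m <- t(matrix(vapply(results, fn, numeric(length(est_names))),
                  nrow = length(est_names)))
    colnames(m) <- est_names
    m
  }
  fm <- per_rep(function(r) colMeans(r$f_table))
  fv <- per_rep(function(r) vapply(r$f_table, var, numeric(1)))
  devs <- per_rep(function(r) r$deviation)
  rmse <- sqrt(colMeans(devs^2))
  rmse_se <- if (R >= 2 && n_boot > 0) {
    bs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(R, R, replace = TRUE)
      sqrt(colMeans(devs[idx, , drop = FALSE]^2))
    }, numeric(length(est_names)))
    apply(matrix(bs, nrow = length(est_names)), 1, stats::sd)
  } else rep(NA_real_, length(est_names))
  qs <- apply(devs, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  k <- ncol(results[[1]]$corr)
  corrs <- array(vapply(results, function(r) r$corr, numeric(k * k)),
                 dim = c(k, k, R),
                 dimnames = c(dimnames(results[[1]]$corr), list(NULL)))
  se <- function(m) apply(m, 2, stats::sd) / sqrt(R)
  structure(list(
    n_replicates = R,
    f_mean = colMeans(fm), f_mean_se = se(fm),
    f_var = colMeans(fv), f_var_se = se(fv),
    true_id_mean = mean(vapply(results, `[[`, numeric(1), "true_id")),
    deviation = data.frame(
      estimator = est_names,
      mean = colMeans(devs), se = se(devs),
      q2.5 = qs[1, ], q97.5 = qs[2, ],
      rmse = rmse, rmse_se = rmse_se,
      row.names = NULL
    ),
    corr_mean = apply(corrs, c(1, 2), mean),
    corr_se = apply(corrs, c(1, 2), stats::sd) / sqrt(R)
  ), class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("scenario_summary over %d replicates (mean true ID %.4g)\n",
              x$n_replicates, x$true_id_mean))
  cat("\nMean / variance of F measures:\n")
  print(round(rbind(mean = x$f_mean, variance = x$f_var), 4))
  cat("\nID estimation (proportional deviation from true ID):\n")
  print(transform(x$deviation,
                  mean = round(mean, 3), se = round(se, 3),
                  q2.5 = round(q2.5, 3), q97.5 = round(q97.5, 3),
                  rmse = round(rmse, 3), rmse_se = round(rmse_se, 3)))
  invisible(x)
}

#' Run a replicated scenario end to end
#'
#' Executes [run_replicate()] followed by [analyze_replicate()] for
#' each seed and aggregates the results.  Fully reproducible from the
#' seed list; failed replicates (e.g. degenerate fitness) are logged
#' and excluded with a reported count.
#'
#' @param config a calibrated [sim_config()].
#' @param n_replicates number of replicates.
#' @param seeds optional integer seed per replicate; derived from
#'   `config$seed` when `NULL`.
#' @param keep_populations keep the final populations (memory-heavy).
#' @param ... passed to [analyze_replicate()].
#' @return list with `summary` (a `scenario_summary`), `replicates`
#'   (the per-replicate results), `seeds`, `n_failed`, `failures`.
#' @export
run_scenario <- function(config, n_replicates, seeds = NULL,
                         keep_populations = FALSE, ...) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  if (is.null(seeds)) {
    set.seed(config$seed)
    seeds <- sample.int(.Machine$integer.max, n_replicates)
  }
  stopifnot(length(seeds) == n_replicates)
  results <- list()
  pops <- list()
  failures <- character(0)
  for (i in seq_len(n_replicates)) {
    res <- tryCatch({
      pop <- run_replicate(config, seed = seeds[i])
      r <- analyze_replicate(pop, ...)
      if (keep_populations) pops[[length(pops) + 1L]] <- pop
      r
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("seed %d: %s", seeds[i],
                                      conditionMessage(res)))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (length(results) == 0) stop("all replicates failed")
  if (length(failures) > 0)
    warning(sprintf("%d replicate(s) failed and were excluded",
                    length(failures)))
  out <- list(summary = aggregate_replicates(results),
              replicates = results, seeds = seeds,
              n_failed = length(failures), failures = failures)
  if (keep_populations) out$populations <- pops
  out
}
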