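#' Power-analysis configuration
#'
#' @param sim a [sim_config()] describing the simulated sample (size,
#'   family mixture, variant MAF, effect size, heritability, phenotype
#'   location/scale and truncation).
#' @param n_reps number of Monte-Carlo replicates (default 1000).
#' @param alpha per-test significance level (default .05/11, the
#'   Bonferroni-corrected level for 11 candidate variants).
#' @param master_seed integer master seed; the pedigree and the
#'   per-replicate seeds are derived from it deterministically.
#' @param keep_pvalues archive per-replicate p-values in the result.
#' @return list of class `power_config`.
#' @export
power_config <- function(sim, n_reps = 1000, alpha = bonferroni_alpha(0.05, 11),
                         master_seed = 1L, keep_pvalues = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  if (n_reps < 1) stop("n_reps must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(sim = sim, n_reps = as.integer(n_reps), alpha = alpha,
                 master_seed = as.integer(master_seed),
                 keep_pvalues = keep_pvalues),
            class = "power_config")
}

# per-replicate seed streams: a single draw of n seeds under the master
# seed, so replicate i is reproducible in isolation
replicate_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2147483646L, n)
}

#' Monte-Carlo power of the mixed-model variant test
#'
#' Estimates the power to detect a variant explaining a given fraction of
#' phenotypic variance in a family-structured sample with a truncated
#' MET-hours phenotype. One pedigree is generated per run (family
#' composition is a nuisance parameter); each replicate gene-drops the
#' variant anew, simulates the phenotype with additive-genetic familial
#' covariance and truncation, fits the maximum-likelihood mixed model with
#' intercept and variant only (no sex/age — estimates are conservative, as
#' in the study design being emulated) and a relationship-matrix random
#' effect, and records the Wald p-value of the variant. Power is the
#' fraction of replicates with p below `alpha`, with a 95%
#' normal-approximation binomial confidence interval.
#'
#' @param config a [power_config()].
#' @return list of class `power_result`: `power`, `ci_low`, `ci_high`,
#'   `n_reps`, `n_failed`, `n_individuals`, `n_families`, `config`, and
#'   optionally `p_values`.
#' @export
estimate_power <- function(config) {
  stopifnot(inherits(config, "power_config"))
  sim <- config$sim
  ped <- generate_families(sim)
  plan <- genedrop_plan(ped)
  decomp <- kinship_decomp(ped)
  n <- length(decomp$ids)
  samp_idx <- match(decomp$ids, ped$individual_id)
  X <- cbind(`(Intercept)` = rep(1, n), g = 0)
  seeds <- replicate_seeds(config$master_seed, config$n_reps)
  pvals <- rep(NA_real_, config$n_reps)
  for (i in seq_len(config$n_reps)) {
    set.seed(seeds[i])
    gfull <- genedrop_run(plan, sim$maf)
    g <- gfull[samp_idx]
    y0 <- latent_phenotype(g, sim, decomp)
    y <- pmin(pmax(sim$phenotype_mean + sim$phenotype_sd * y0, sim$floor),
              sim$cap)
    X[, 2] <- g
    fit <- tryCatch(lmm_fit_core(y, X, decomp), error = function(e) NULL)
    if (!is.null(fit)) pvals[i] <- fit$wald$p_value[2]
  }
  failed <- sum(is.na(pvals))
  if (failed > 0.05 * config$n_reps)
    stop(sprintf("power run invalid: %d of %d replicate fits failed",
                 failed, config$n_reps))
  ok <- !is.na(pvals)
  hits <- sum(pvals[ok] < config$alpha)
  ci <- binomial_ci(hits, sum(ok))
  res <- list(power = hits / sum(ok), ci_low = ci[1], ci_high = ci[2],
              n_reps = sum(ok), n_failed = failed,
              n_individuals = n, n_families = length(unique(decomp$family)),
              config = config)
  if (config$keep_pvalues) res$p_values <- pvals
  structure(res, class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "power = %.3f (95%% CI %.3f-%.3f), %d replicates (%d failed), N = %d in %d families\n",
    x$power, x$ci_low, x$ci_high, x$n_reps, x$n_failed,
    x$n_individuals, x$n_families))
  invisible(x)
}

#' Normal-approximation binomial confidence interval
#'
#' Wald interval \eqn{\hat p \pm z \sqrt{\hat p (1-\hat p)/n}}, clipped to
#' \eqn{[0, 1]}; a Wilson interval is available as an option.
#'
#' @param successes number of successes.
#' @param n number of trials.
#' @param level confidence level (default .95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return numeric `c(low, high)`.
#' @export
binomial_ci <- function(successes, n, level = 0.95,
                        method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (n < 1 || successes < 0 || successes > n)
    stop("need 0 <= successes <= n and n >= 1")
  p <- successes / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    out <- c(p - half, p + half)
  } else {
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    out <- c(ctr - half, ctr + half)
  }
  pmin(pmax(out, 0), 1)
}

#' Power across a grid of scenarios
#'
#' Runs [estimate_power()] for each configuration and tabulates the
#' results; deterministic given the configurations' master seeds.
#'
#' @param configs list of [power_config()] objects.
#' @return data frame with one row per scenario: sample size, MAF, effect
#'   size, heritability, alpha, replicates, power and its 95% CI.
#' @export
power_table <- function(configs) {
  if (!length(configs)) stop("need at least one configuration")
  if (inherits(configs, "power_config")) configs <- list(configs)
  rows <- lapply(configs, function(cf) {
    res <- estimate_power(cf)
    data.frame(n_individuals = res$n_individuals,
               n_families = res$n_families,
               maf = cf$sim$maf, effect_r2 = cf$sim$effect_r2,
               h2 = cf$sim$h2, alpha = cf$alpha, n_reps = res$n_reps,
               power = res$power, ci_low = res$ci_low,
               ci_high = res$ci_high)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
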