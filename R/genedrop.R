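#' Drop a biallelic variant through a pedigree
#'
#' Simulates genotypes by gene dropping: founders receive allele counts
#' drawn under Hardy-Weinberg equilibrium at frequency `maf`; every
#' non-founder receives one allele from each parent, each transmitted
#' allele being a Bernoulli draw with probability equal to half the
#' parent's allele count (exact for unphased biallelic transmission).
#' MZ co-twins receive identical genotypes.
#'
#' @param ped a `twin_pedigree`.
#' @param maf founder allele frequency of the counted allele, in \eqn{[0, 1)}.
#' @param seed integer seed; `NULL` to use the current RNG state.
#' @return named integer vector of 0/1/2 counted-allele counts for every
#'   individual in the pedigree (sampled or not).
#' @export
gene_drop <- function(ped, maf, seed = NULL) {
  stopifnot(inherits(ped, "twin_pedigree"))
  if (maf < 0 || maf >= 1) stop("maf must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  plan <- genedrop_plan(ped)
  g <- genedrop_run(plan, maf)
  stats::setNames(g, ped$individual_id)
}

# Precompute transmission bookkeeping so repeated drops through the same
# pedigree are pure rbinom calls.
genedrop_plan <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$individual_id)
  mo <- match(ped$mother_id, ped$individual_id)
  if (any(xor(is.na(fa), is.na(mo))))
    stop("pedigree error: non-founder with a missing parent record")
  gen <- pedigree_generations(fa, mo)
  # MZ groups: same family + same parents; the first member is drawn, the
  # rest copy it.
  copy_src <- rep(NA_integer_, n)
  mz <- which(ped$zygosity == "MZ" & !is.na(fa))
  if (length(mz)) {
    key <- paste(ped$family_id[mz], fa[mz], mo[mz])
    for (grp in split(mz, key)) {
      if (length(grp) >= 2) copy_src[grp[-1]] <- grp[1]
    }
  }
  gen_groups <- split(seq_len(n), gen)
  list(n = n, fa = fa, mo = mo, gen_groups = gen_groups, copy_src = copy_src,
       sampled = which(ped$sampled))
}

genedrop_run <- function(plan, maf) {
  g <- integer(plan$n)
  for (k in seq_along(plan$gen_groups)) {
    idx <- plan$gen_groups[[k]]
    if (k == 1L) {
      g[idx] <- stats::rbinom(length(idx), 2L, maf)
    } else {
      g[idx] <- stats::rbinom(length(idx), 1L, g[plan$fa[idx]] / 2) +
                stats::rbinom(length(idx), 1L, g[plan$mo[idx]] / 2)
    }
    cp <- idx[!is.na(plan$copy_src[idx])]
    if (length(cp)) g[cp] <- g[plan$copy_src[cp]]
  }
  g
}

#' Simulate a truncated MET-hours phenotype on a pedigree
#'
#' Builds a latent unit-variance phenotype as the sum of (i) a variant
#' effect scaled so that it explains `effect_r2` of the latent variance
#' (using variant variance \eqn{2 maf (1-maf)} under HWE), (ii) an additive
#' genetic deviate with covariance `h2` times the relationship matrix, and
#' (iii) an independent Gaussian residual. The latent score is mapped to
#' `phenotype_mean` and `phenotype_sd` MET hours, floored at `floor` and
#' capped at `cap`, emulating a right-skewed exercise score truncated at
#' 120 MET hours.
#'
#' @param ped a `twin_pedigree`.
#' @param genotype named 0/1/2 vector from [gene_drop()] (must cover the
#'   sampled individuals).
#' @param config a [sim_config()].
#' @param decomp optional precomputed [kinship_decomp()] for the sampled
#'   individuals (computed if omitted).
#' @param seed integer seed; `NULL` to use the current RNG state.
#' @return named numeric vector of MET hours for the sampled individuals.
#' @export
simulate_phenotype <- function(ped, genotype, config, decomp = NULL,
                               seed = NULL) {
  stopifnot(inherits(ped, "twin_pedigree"), inherits(config, "sim_config"))
  if (config$effect_r2 + config$h2 >= 1)
    stop("configuration error: effect_r2 + h2 must be < 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(decomp)) decomp <- kinship_decomp(ped)
  ids <- decomp$ids
  if (!all(ids %in% names(genotype)))
    stop("genotype vector does not cover the sampled individuals")
  g <- genotype[ids]
  y0 <- latent_phenotype(g, config, decomp)
  y <- config$phenotype_mean + config$phenotype_sd * y0
  y <- pmin(pmax(y, config$floor), config$cap)
  stats::setNames(y, ids)
}

# latent unit-variance score; consumes RNG
latent_phenotype <- function(g, config, decomp) {
  n <- length(g)
  pq2 <- 2 * config$maf * (1 - config$maf)
  b <- if (config$effect_r2 > 0 && pq2 > 0) sqrt(config$effect_r2 / pq2) else 0
  a <- as.numeric(decomp$U %*% (sqrt(decomp$d) * stats::rnorm(n)))
  e <- stats::rnorm(n)
  b * (g - 2 * config$maf) + sqrt(config$h2) * a +
    sqrt(1 - config$effect_r2 - config$h2) * e
}
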