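#' Twin-family pedigrees
#'
#' A pedigree is a data frame with one row per individual and columns
#' `family_id`, `individual_id`, `father_id`, `mother_id` (`NA` for
#' founders), `sex` (1 = male, 2 = female), `zygosity` (`"MZ"`, `"DZ"` or
#' `"none"`), `age` (years) and `sampled` (logical: whether the individual
#' belongs to the analysis sample or is only an allele source, such as an
#' ungenotyped parent of twins). Rows are ordered so that parents precede
#' their offspring.
#'
#' @param df data frame with at least the columns above (`age` and
#'   `sampled` are filled with `NA`/`TRUE` when absent).
#' @return a validated pedigree (class `twin_pedigree`).
#' @export
new_pedigree <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("family_id", "individual_id", "father_id", "mother_id",
                "sex", "zygosity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"age" %in% names(df)) df$age <- NA_real_
  if (!"sampled" %in% names(df)) df$sampled <- TRUE
  df$family_id <- as.character(df$family_id)
  df$individual_id <- as.character(df$individual_id)
  df$father_id <- as.character(df$father_id)
  df$mother_id <- as.character(df$mother_id)
  df$father_id[df$father_id %in% c("0", "")] <- NA_character_
  df$mother_id[df$mother_id %in% c("0", "")] <- NA_character_
  validate_pedigree(df)
  df <- order_pedigree(df)
  class(df) <- c("twin_pedigree", "data.frame")
  df
}

validate_pedigree <- function(df) {
  if (anyDuplicated(df$individual_id)) {
    dup <- unique(df$individual_id[duplicated(df$individual_id)])
    stop("duplicate individual ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (!all(df$sex %in% c(1L, 2L)))
    stop("sex must be coded 1 (male) or 2 (female)")
  if (!all(df$zygosity %in% c("MZ", "DZ", "none")))
    stop("zygosity must be one of MZ, DZ, none")
  fam_of <- stats::setNames(df$family_id, df$individual_id)
  for (col in c("father_id", "mother_id")) {
    p <- df[[col]]
    known <- is.na(p) | p %in% df$individual_id
    if (!all(known))
      stop("unknown ", col, " reference(s): ",
           paste(utils::head(unique(p[!known]), 5), collapse = ", "))
    present <- !is.na(p)
    if (any(p[present] == df$individual_id[present]))
      stop("individual listed as its own parent")
    if (any(fam_of[p[present]] != df$family_id[present]))
      stop("parent assigned to a different family than the child")
  }
  one_parent <- xor(is.na(df$father_id), is.na(df$mother_id))
  if (any(one_parent))
    stop("individuals with exactly one recorded parent: ",
         paste(utils::head(df$individual_id[one_parent], 5), collapse = ", "))
  # MZ co-twins must share both parents
  mz <- df[df$zygosity == "MZ", , drop = FALSE]
  if (nrow(mz)) {
    key <- paste(mz$family_id, mz$father_id, mz$mother_id)
    sizes <- table(key)
    if (any(sizes < 2))
      stop("MZ-tagged individual without a co-twin sharing both parents")
  }
  ages <- df$age[!is.na(df$age)]
  if (length(ages) && (any(ages < 7) || any(ages > 50)))
    stop("ages must lie within [7, 50]")
  invisible(df)
}

# topological order (parents first); errors on parent-link cycles
order_pedigree <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n)
  fa <- match(df$father_id, df$individual_id)
  mo <- match(df$mother_id, df$individual_id)
  gen <- pedigree_generations(fa, mo)
  out <- df[order(df$family_id, gen, idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

pedigree_generations <- function(fa, mo) {
  n <- length(fa)
  gen <- ifelse(is.na(fa) & is.na(mo), 0L, NA_integer_)
  repeat {
    pending <- which(is.na(gen))
    if (!length(pending)) break
    ready <- pending[!is.na(gen[fa[pending]]) & !is.na(gen[mo[pending]])]
    if (!length(ready))
      stop("cycle in pedigree parent links")
    gen[ready] <- pmax(gen[fa[ready]], gen[mo[ready]]) + 1L
  }
  gen
}

#' @export
print.twin_pedigree <- function(x, ...) {
  cat(sprintf("twin pedigree: %d individuals (%d sampled) in %d families\n",
              nrow(x), sum(x$sampled), length(unique(x$family_id))))
  print(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

# Family templates. `sampled_size` counts analysis individuals; parents of
# twins are generated as implicit founders (allele sources) and flagged
# sampled = FALSE.
family_templates <- function() {
  list(
    mz_pair  = list(sampled_size = 2L, twins = "MZ", extra_sib = 0L),
    dz_pair  = list(sampled_size = 2L, twins = "DZ", extra_sib = 0L),
    dz_sib   = list(sampled_size = 3L, twins = "DZ", extra_sib = 1L),
    single   = list(sampled_size = 1L, twins = "none", extra_sib = 0L)
  )
}

#' Default family-composition mixture
#'
#' Mixture weights over family templates used when simulating twin-register
#' style samples: mostly twin pairs with equal monozygotic/dizygotic shares,
#' a sizeable fraction of twin pairs with an additional full sibling, and a
#' few singleton participants. The weights are calibrated so the mean number
#' of analysed individuals per family is 2.25, matching a register of 8,768
#' participants in 3,900 families.
#'
#' @return named numeric vector of weights summing to 1.
#' @export
default_family_mixture <- function() {
  c(mz_pair = 0.325, dz_pair = 0.325, dz_sib = 0.30, single = 0.05)
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic twin-family generator: sample
#' size, family-composition mixture, variant allele frequency, the fraction
#' of phenotypic variance explained by the variant, narrow-sense
#' heritability, and the marginal location/scale and truncation of the
#' weekly MET-hours phenotype.
#'
#' @param n_individuals target number of analysed individuals (`NULL` to
#'   derive from `n_families`).
#' @param n_families target number of families (`NULL` to derive from
#'   `n_individuals`).
#' @param mixture named weights over family templates (see
#'   [default_family_mixture()]).
#' @param maf variant allele frequency in founders, in \eqn{[0, 1)}.
#' @param effect_r2 fraction of (latent, pre-truncation) phenotypic variance
#'   explained by the variant.
#' @param h2 narrow-sense heritability of the residual familial background.
#' @param phenotype_mean,phenotype_sd location and scale of the latent
#'   phenotype, in MET hours (defaults 13 and 18).
#' @param floor lower truncation bound in MET hours (default 0; `-Inf` to
#'   disable).
#' @param cap upper truncation bound in MET hours (default 120; `Inf` to
#'   disable).
#' @param seed integer seed for pedigree generation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = NULL, n_families = NULL,
                       mixture = default_family_mixture(),
                       maf = 0.2, effect_r2 = 0, h2 = 0.55,
                       phenotype_mean = 13, phenotype_sd = 18,
                       floor = 0, cap = 120, seed = 1L) {
  if (is.null(n_individuals) && is.null(n_families))
    stop("configuration error: give n_individuals and/or n_families")
  if (maf < 0 || maf >= 1) stop("configuration error: maf must be in [0, 1)")
  if (effect_r2 < 0 || h2 < 0 || effect_r2 + h2 >= 1)
    stop("configuration error: effect_r2 + h2 must be < 1 (both nonnegative)")
  if (cap <= 0) stop("configuration error: cap must be positive")
  if (abs(sum(mixture) - 1) > 1e-8)
    stop("configuration error: mixture weights must sum to 1")
  if (!all(names(mixture) %in% names(family_templates())))
    stop("configuration error: unknown template in mixture: ",
         paste(setdiff(names(mixture), names(family_templates())), collapse = ", "))
  structure(list(n_individuals = n_individuals, n_families = n_families,
                 mixture = mixture, maf = maf, effect_r2 = effect_r2, h2 = h2,
                 phenotype_mean = phenotype_mean, phenotype_sd = phenotype_sd,
                 floor = floor, cap = cap, seed = as.integer(seed)),
            class = "sim_config")
}

# Allocate per-template family counts so that the family total is exactly
# n_families and the sampled-individual total is as close as possible to
# n_individuals (always within one template size).
allocate_templates <- function(n_individuals, n_families, mixture) {
  tmpl <- family_templates()
  sizes <- vapply(tmpl[names(mixture)], `[[`, integer(1), "sampled_size")
  mean_size <- sum(mixture * sizes)
  if (is.null(n_families)) n_families <- as.integer(round(n_individuals / mean_size))
  if (is.null(n_individuals)) n_individuals <- as.integer(round(n_families * mean_size))
  n_families <- as.integer(n_families)
  if (n_families < 1) stop("configuration error: need at least one family")
  lo <- n_families * min(sizes[mixture > 0])
  hi <- n_families * max(sizes[mixture > 0])
  if (n_individuals < lo || n_individuals > hi)
    stop(sprintf(
      "configuration error: %d families of the given templates can hold %d-%d individuals, not %d",
      n_families, lo, hi, n_individuals))
  # largest-remainder rounding to n_families
  exact <- mixture * n_families
  counts <- floor(exact)
  rem <- n_families - sum(counts)
  if (rem > 0) {
    take <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[take] <- counts[take] + 1
  }
  counts <- stats::setNames(as.integer(counts), names(mixture))
  # repair the individual total by moving families between size classes
  total <- sum(counts * sizes)
  grow <- order(sizes)                      # indices by size ascending
  while (total != n_individuals) {
    if (total < n_individuals) {
      # promote one family from a smaller class to the next larger one
      from <- which(counts > 0 & sizes < max(sizes[mixture > 0]))
      if (!length(from)) break
      from <- from[which.max(sizes[from])]
      to <- which(sizes > sizes[from] & mixture >= 0)
      to <- to[which.min(sizes[to])]
    } else {
      from <- which(counts > 0 & sizes > min(sizes[mixture > 0]))
      if (!length(from)) break
      from <- from[which.min(sizes[from])]
      to <- which(sizes < sizes[from])
      to <- to[which.max(sizes[to])]
    }
    counts[from] <- counts[from] - 1L
    counts[to] <- counts[to] + 1L
    total <- sum(counts * sizes)
  }
  counts
}

#' Generate synthetic twin families
#'
#' Draws a pedigree of twin-register style families from a mixture of
#' family templates (MZ twin pair, DZ twin pair, DZ pair plus one full
#' sibling, singleton). Twin and sibling families include their two parents
#' as unsampled founders so that genotypes can be dropped through the
#' pedigree; singletons are sampled founders. Ages are drawn uniformly on
#' \[18, 50\] (co-twins share their age), MZ co-twins share sex.
#'
#' @param config a [sim_config()]; its `n_individuals`/`n_families`,
#'   `mixture` and `seed` fields are used.
#' @return a `twin_pedigree` whose sampled individuals number within one
#'   family-template size of the requested total.
#' @export
generate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  counts <- allocate_templates(config$n_individuals, config$n_families,
                               config$mixture)
  tmpl <- family_templates()
  types <- sample(rep(names(counts), counts))  # seeded shuffle
  nfam <- length(types)
  rows <- vector("list", nfam)
  for (f in seq_len(nfam)) {
    ty <- types[f]
    tm <- tmpl[[ty]]
    fid <- sprintf("F%05d", f)
    age <- round(stats::runif(1, 18, 50), 1)
    if (ty == "single") {
      rows[[f]] <- data.frame(
        family_id = fid, individual_id = paste0(fid, "_I1"),
        father_id = NA_character_, mother_id = NA_character_,
        sex = sample(1:2, 1), zygosity = "none", age = age, sampled = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    fa <- paste0(fid, "_FA"); mo <- paste0(fid, "_MO")
    twin_sex <- if (tm$twins == "MZ") rep(sample(1:2, 1), 2) else sample(1:2, 2, replace = TRUE)
    ids <- paste0(fid, "_T", 1:2)
    fam <- data.frame(
      family_id = fid,
      individual_id = c(fa, mo, ids),
      father_id = c(NA, NA, fa, fa),
      mother_id = c(NA, NA, mo, mo),
      sex = c(1L, 2L, twin_sex),
      zygosity = c("none", "none", tm$twins, tm$twins),
      age = c(NA, NA, age, age),
      sampled = c(FALSE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE)
    if (tm$extra_sib > 0) {
      sib_age <- min(50, max(18, age + sample(c(-4:-2, 2:4), 1)))
      fam <- rbind(fam, data.frame(
        family_id = fid, individual_id = paste0(fid, "_S1"),
        father_id = fa, mother_id = mo, sex = sample(1:2, 1),
        zygosity = "none", age = sib_age, sampled = TRUE,
        stringsAsFactors = FALSE))
    }
    rows[[f]] <- fam
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  ped <- new_pedigree(ped)
  attr(ped, "template_counts") <- counts
  ped
}

#' Additive genetic relationship matrix
#'
#' Computes the expected additive genetic relationship (twice the kinship
#' coefficient) between individuals by the tabular method, processing each
#' family independently; the result is block-diagonal by family. MZ co-twins
#' are treated as genetically identical (relationship 1 with each other,
#' and identical relationships to everyone else). No inbreeding is assumed
#' beyond what the parent links imply.
#'
#' @param ped a `twin_pedigree`.
#' @param ids individuals to include, in the returned order; defaults to
#'   the sampled individuals.
#' @return sparse symmetric matrix (`Matrix::dsCMatrix`) with `dimnames`
#'   equal to `ids`.
#' @export
relationship_matrix <- function(ped, ids = ped$individual_id[ped$sampled]) {
  stopifnot(inherits(ped, "twin_pedigree"))
  if (!all(ids %in% ped$individual_id))
    stop("pedigree error: unknown individual id(s) in `ids`")
  fam <- split(seq_len(nrow(ped)), ped$family_id)
  blocks <- lapply(fam, function(rows) family_A_block(ped[rows, , drop = FALSE]))
  A_all <- Matrix::bdiag(blocks)
  all_ids <- unlist(lapply(fam, function(rows) ped$individual_id[rows]),
                    use.names = FALSE)
  dimnames(A_all) <- list(all_ids, all_ids)
  out <- A_all[ids, ids, drop = FALSE]
  methods::as(Matrix::forceSymmetric(out), "symmetricMatrix")
}

# dense A block for one family's rows (already parents-first ordered)
family_A_block <- function(fd) {
  n <- nrow(fd)
  fa <- match(fd$father_id, fd$individual_id)
  mo <- match(fd$mother_id, fd$individual_id)
  if (any(xor(is.na(fa), is.na(mo))))
    stop("pedigree error: individual with one recorded parent")
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    if (is.na(fa[j])) {
      A[j, j] <- 1
    } else {
      if (fa[j] >= j || mo[j] >= j)
        stop("pedigree error: parents must precede offspring")
      for (i in seq_len(j - 1L))
        A[i, j] <- A[j, i] <- 0.5 * (A[i, fa[j]] + A[i, mo[j]])
      A[j, j] <- 1 + 0.5 * A[fa[j], mo[j]]
    }
  }
  # MZ co-twins: genetically identical
  mz <- which(fd$zygosity == "MZ")
  if (length(mz) >= 2) {
    key <- paste(fd$father_id[mz], fd$mother_id[mz])
    for (grp in split(mz, key)) {
      if (length(grp) < 2) next
      first <- grp[1]
      for (tw in grp[-1]) {
        A[tw, ] <- A[first, ]
        A[, tw] <- A[, first]
        A[tw, tw] <- A[first, first]
        A[first, tw] <- A[tw, first] <- A[first, first]
      }
    }
  }
  A
}

#' Family-block spectral decomposition of the relationship matrix
#'
#' Eigendecomposes the additive relationship matrix family by family and
#' assembles a sparse orthogonal matrix `U` and eigenvalue vector `d` with
#' `A = U diag(d) U'`. Because `A` is block-diagonal, rotating data by `U'`
#' diagonalises the mixed-model covariance, so likelihood evaluations cost
#' O(n); the decomposition is computed once per pedigree and reused across
#' model fits and simulation replicates.
#'
#' @param ped a `twin_pedigree` (or a symmetric relationship matrix with
#'   dimnames).
#' @param ids individuals to include; defaults to sampled individuals.
#' @return list of class `kinship_decomp` with elements `U` (sparse n x n),
#'   `d` (eigenvalues), `ids`, `family` (family id per individual).
#' @export
kinship_decomp <- function(ped, ids = NULL) {
  if (inherits(ped, "twin_pedigree")) {
    if (is.null(ids)) ids <- ped$individual_id[ped$sampled]
    fam_of <- stats::setNames(ped$family_id, ped$individual_id)[ids]
    A <- relationship_matrix(ped, ids)
  } else {
    A <- ped
    if (is.null(dimnames(A)[[1]])) dimnames(A) <- list(seq_len(nrow(A)), seq_len(nrow(A)))
    if (is.null(ids)) ids <- dimnames(A)[[1]]
    A <- A[ids, ids, drop = FALSE]
    fam_of <- connected_blocks(A)
  }
  n <- length(ids)
  ord <- order(match(fam_of, unique(fam_of)))
  ids_o <- ids[ord]
  fam_o <- fam_of[ord]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  d <- numeric(n)
  offset <- 0L
  for (rows in split(seq_len(n), match(fam_o, unique(fam_o)))) {
    k <- length(rows)
    Ab <- as.matrix(A[ids_o[rows], ids_o[rows], drop = FALSE])
    eg <- eigen(Ab, symmetric = TRUE)
    d[offset + seq_len(k)] <- pmax(eg$values, 0)
    ii <- c(ii, rep(offset + seq_len(k), each = k))
    jj <- c(jj, rep(offset + seq_len(k), times = k))
    xx <- c(xx, as.numeric(eg$vectors))  # column-major: rows vary fastest
    offset <- offset + k
  }
  U <- Matrix::sparseMatrix(i = jj, j = ii, x = xx, dims = c(n, n))
  # map back to requested id order: we keep the permuted order internally
  structure(list(U = U, d = d, ids = ids_o, family = fam_o),
            class = "kinship_decomp")
}

# label connected components of a symmetric matrix (fallback when only a
# matrix, not a pedigree, is supplied)
connected_blocks <- function(A) {
  n <- nrow(A)
  lab <- integer(n)
  cur <- 0L
  nz <- abs(as.matrix(A)) > 1e-12
  for (s in seq_len(n)) {
    if (lab[s]) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (lab[v]) next
      lab[v] <- cur
      queue <- c(queue, which(nz[v, ] & lab == 0L))
    }
  }
  stats::setNames(paste0("B", lab), dimnames(A)[[1]])
}
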