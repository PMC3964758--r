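#' Variant specification
#'
#' Metadata for a SNP or VNTR: its alleles, which allele is counted in the
#' additive 0/1/2 coding (for VNTRs, the focal repeat — e.g. the DRD4
#' 7-repeat, the DRD5 148-bp allele or the DAT1 480-bp allele), and which
#' allele is hypothesised to increase dopamine signalling (the "effect
#' allele" used in the polygenic risk score).
#'
#' @param variant_id variant identifier (e.g. `"rs4680"`).
#' @param kind `"snp"` or `"vntr"`.
#' @param alleles character vector of allele labels.
#' @param counted_allele the allele whose copies give the 0/1/2 code; for a
#'   VNTR this is the focal repeat.
#' @param effect_allele dopamine-increasing allele, one of `alleles` or
#'   `"absence-of-focal"` when the hypothesis is that *lacking* the focal
#'   repeat raises dopamine.
#' @param gene gene symbol.
#' @return list of class `variant_spec`.
#' @export
variant_spec <- function(variant_id, kind = c("snp", "vntr"), alleles,
                         counted_allele, effect_allele = NA_character_,
                         gene = NA_character_) {
  kind <- match.arg(kind)
  alleles <- as.character(alleles)
  counted_allele <- as.character(counted_allele)
  if (!counted_allele %in% alleles)
    stop("counted_allele must be one of the allele labels")
  if (!is.na(effect_allele) &&
      !(effect_allele %in% alleles || effect_allele == "absence-of-focal"))
    stop("effect_allele must be an allele label or \"absence-of-focal\"")
  structure(list(variant_id = variant_id, kind = kind, alleles = alleles,
                 counted_allele = counted_allele,
                 effect_allele = effect_allele, gene = gene),
            class = "variant_spec")
}

#' Code SNP genotypes additively
#'
#' Converts per-individual allele pairs into 0/1/2 counts of the variant's
#' counted allele.
#'
#' @param pairs two-column character matrix (or data frame) of alleles, one
#'   row per individual; `NA` rows give missing codes.
#' @param spec a [variant_spec()].
#' @return integer vector of codes (with `NA` for missing), plus the spec
#'   as attribute `"variant"`.
#' @export
code_snp <- function(pairs, spec) {
  stopifnot(inherits(spec, "variant_spec"))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("allele pairs must have two columns")
  miss <- is.na(pairs[, 1]) | is.na(pairs[, 2])
  bad <- !miss & (!(pairs[, 1] %in% spec$alleles) | !(pairs[, 2] %in% spec$alleles))
  if (any(bad))
    stop("data error: allele(s) not in spec for ", spec$variant_id, ": ",
         paste(utils::head(unique(as.vector(pairs[bad, ])), 5), collapse = ", "))
  code <- (pairs[, 1] == spec$counted_allele) + (pairs[, 2] == spec$counted_allele)
  code[miss] <- NA_integer_
  structure(as.integer(code), variant = spec, names = rownames(pairs))
}

#' Code VNTR genotypes as focal-repeat counts
#'
#' Counts copies of the focal repeat allele (0 = no copy, 1 = one copy,
#' 2 = two copies); any pair of non-focal repeats codes 0 regardless of
#' which repeats they are.
#'
#' @inheritParams code_snp
#' @return integer vector of codes as for [code_snp()].
#' @export
code_vntr <- function(pairs, spec) {
  stopifnot(inherits(spec, "variant_spec"))
  if (spec$kind != "vntr") stop("spec is not a VNTR")
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("repeat pairs must have two columns")
  pairs[] <- as.character(pairs)
  miss <- is.na(pairs[, 1]) | is.na(pairs[, 2])
  bad <- !miss & (!(pairs[, 1] %in% spec$alleles) | !(pairs[, 2] %in% spec$alleles))
  if (any(bad))
    stop("data error: repeat allele(s) not in spec for ", spec$variant_id)
  code <- (pairs[, 1] == spec$counted_allele) + (pairs[, 2] == spec$counted_allele)
  code[miss] <- NA_integer_
  structure(as.integer(code), variant = spec, names = rownames(pairs))
}

#' Minor allele frequency
#'
#' Frequency of the counted allele is `sum(codes) / (2 * N)` over
#' non-missing hard calls (mean dosage / 2 in dosage mode); the reported
#' MAF folds to `min(f, 1 - f)`.
#'
#' @param codes 0/1/2 codes or dosages in \eqn{[0, 2]}, `NA` allowed.
#' @param folded return the folded (minor) frequency (default `TRUE`).
#' @return allele frequency.
#' @export
maf <- function(codes, folded = TRUE) {
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("undefined value: all genotypes missing")
  if (any(codes < 0 | codes > 2)) stop("codes must lie in [0, 2]")
  f <- sum(codes) / (2 * length(codes))
  if (folded) min(f, 1 - f) else f
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests observed genotype counts against the proportions expected under
#' Hardy-Weinberg equilibrium at the sample allele frequency. The default
#' is the Pearson chi-square test with 1 df and no continuity correction;
#' `method = "exact"` gives the standard exact test (summing probabilities
#' of heterozygote counts no more likely than the observed one,
#' conditional on the allele counts). A monomorphic sample is in perfect
#' equilibrium by convention and returns p = 1.
#'
#' @param counts length-3 vector of genotype counts `(n0, n1, n2)` for the
#'   0-, 1- and 2-copy classes.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return p-value in \eqn{[0, 1]}.
#' @export
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (length(counts) != 3 || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be three nonnegative integers (n0, n1, n2)")
  n0 <- counts[1]; n1 <- counts[2]; n2 <- counts[3]
  n <- n0 + n1 + n2
  if (n < 1) stop("need at least one genotype")
  nA <- n1 + 2 * n2
  if (nA == 0 || nA == 2 * n) return(1)
  if (method == "chisq") {
    p <- nA / (2 * n)
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    x2 <- sum((counts - expd)^2 / expd)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  hwe_exact(n0, n1, n2)
}

# exact HWE: conditional distribution of the heterozygote count given the
# minor-allele count (Levene/Haldane), two-sided by summing probabilities
# <= that of the observed configuration
hwe_exact <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- n1 + 2 * n2
  nm <- min(nA, 2 * n - nA)           # minor allele count
  het <- seq(nm %% 2, nm, by = 2)     # feasible heterozygote counts
  logp <- lfactorial(n) - lfactorial((nm - het) / 2) - lfactorial(het) -
    lfactorial(n - (nm + het) / 2) + het * log(2) +
    lfactorial(nm) + lfactorial(2 * n - nm) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n1, het)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Mendelian consistency check
#'
#' Counts parent-offspring transmissions that are impossible for a
#' biallelic variant. Every offspring with at least one genotyped parent
#' contributes one informative transmission; a trio is an error when no
#' combination of one allele from each parent can produce the child's
#' code, a duo when parent and child are opposite homozygotes.
#'
#' @param ped a `twin_pedigree`.
#' @param genotypes named 0/1/2 vector over pedigree individuals (`NA` =
#'   untyped). Dosages are refused: Mendelian checks need hard calls.
#' @return list with `errors`, `informative` and `rate` (NaN when no
#'   informative transmissions).
#' @export
mendel_check <- function(ped, genotypes) {
  stopifnot(inherits(ped, "twin_pedigree"))
  g <- genotypes[ped$individual_id]
  if (any(!is.na(g) & g != round(g)))
    stop("Mendelian checks require hard 0/1/2 calls, not dosages")
  fa <- match(ped$father_id, ped$individual_id)
  mo <- match(ped$mother_id, ped$individual_id)
  gc <- as.integer(g)
  gf <- ifelse(is.na(fa), NA_integer_, gc[fa])
  gm <- ifelse(is.na(mo), NA_integer_, gc[mo])
  has_child <- !is.na(gc)
  trio <- has_child & !is.na(gf) & !is.na(gm)
  duo_f <- has_child & !is.na(gf) & is.na(gm)
  duo_m <- has_child & is.na(gf) & !is.na(gm)
  # allele-count range transmissible by a parent with code p: floor(p/2)..ceil(p/2)
  lo <- function(p) p %/% 2L
  hi <- function(p) (p + 1L) %/% 2L
  trio_err <- trio & (gc < lo(gf) + lo(gm) | gc > hi(gf) + hi(gm))
  duo_err <- (duo_f & (gc < lo(gf) | gc > hi(gf) + 1L)) |
             (duo_m & (gc < lo(gm) | gc > hi(gm) + 1L))
  errors <- sum(trio_err, na.rm = TRUE) + sum(duo_err, na.rm = TRUE)
  informative <- sum(trio) + sum(duo_f) + sum(duo_m)
  list(errors = errors, informative = informative,
       rate = if (informative > 0) errors / informative else NaN)
}

#' Concordance between two genotype vectors
#'
#' Fraction of identical hard calls among individuals non-missing in both
#' vectors (e.g. fingerprint-chip vs imputed genotypes for duplicate
#' samples).
#'
#' @param a,b named or positionally aligned 0/1/2 vectors.
#' @return fraction in \eqn{[0, 1]}.
#' @export
concordance <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  } else if (length(a) != length(b)) {
    stop("unnamed vectors must have equal length")
  }
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("undefined value: no jointly non-missing individuals")
  mean(a[keep] == b[keep])
}

#' QC thresholds
#'
#' Default thresholds mirror standard pre-imputation SNP filters: HWE
#' p > 1e-5, MAF > 0.01, Mendelian error rate < 0.02, call rate > 0.95,
#' allele-frequency difference from the reference panel < 0.20 and
#' duplicate concordance >= 0.95.
#'
#' @param hwe_p_min,maf_min,mendel_rate_max,call_rate_min,freq_diff_max,concordance_min
#'   numeric thresholds, all in \eqn{[0, 1]}.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-5, maf_min = 0.01,
                          mendel_rate_max = 0.02, call_rate_min = 0.95,
                          freq_diff_max = 0.20, concordance_min = 0.95) {
  th <- list(hwe_p_min = hwe_p_min, maf_min = maf_min,
             mendel_rate_max = mendel_rate_max, call_rate_min = call_rate_min,
             freq_diff_max = freq_diff_max, concordance_min = concordance_min)
  if (any(unlist(th) < 0 | unlist(th) > 1))
    stop("all thresholds must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Apply QC filters to a set of variants
#'
#' Computes MAF, HWE p, call rate and (when the needed inputs are given)
#' Mendelian error rate, reference allele-frequency difference and
#' duplicate concordance for each variant, and compares them with the
#' thresholds. A variant passes iff every computed metric satisfies its
#' threshold; metrics whose inputs are absent are reported as `NA` and not
#' held against the variant.
#'
#' @param genotypes named list (by variant id) of 0/1/2 code vectors, each
#'   named by individual id.
#' @param ped optional `twin_pedigree` for Mendelian checks.
#' @param reference_freqs optional named vector of reference counted-allele
#'   frequencies.
#' @param duplicates optional named list (by variant id) of second genotype
#'   vectors for concordance.
#' @param thresholds a [qc_thresholds()].
#' @return data frame with one row per variant: metric values, per-metric
#'   verdicts, overall `pass` and a comma-separated `reasons` column for
#'   failures.
#' @export
apply_qc <- function(genotypes, ped = NULL, reference_freqs = NULL,
                     duplicates = NULL, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"), is.list(genotypes))
  rows <- lapply(names(genotypes), function(v) {
    codes <- genotypes[[v]]
    m <- maf(codes)
    cr <- mean(!is.na(codes))
    cnt <- tabulate(factor(round(codes[!is.na(codes)]), levels = 0:2), 3)
    hw <- hwe_test(cnt)
    md <- if (!is.null(ped)) mendel_check(ped, codes)$rate else NA_real_
    fd <- if (!is.null(reference_freqs) && v %in% names(reference_freqs))
      abs(maf(codes, folded = FALSE) - reference_freqs[[v]]) else NA_real_
    cc <- if (!is.null(duplicates) && v %in% names(duplicates))
      concordance(codes, duplicates[[v]]) else NA_real_
    checks <- c(
      maf = m > thresholds$maf_min,
      hwe = hw > thresholds$hwe_p_min,
      call_rate = cr > thresholds$call_rate_min,
      mendel = if (is.na(md) || is.nan(md)) NA else md < thresholds$mendel_rate_max,
      freq_diff = if (is.na(fd)) NA else fd < thresholds$freq_diff_max,
      concordance = if (is.na(cc)) NA else cc >= thresholds$concordance_min)
    failed <- names(checks)[!is.na(checks) & !checks]
    data.frame(variant_id = v, maf = m, hwe_p = hw, call_rate = cr,
               mendel_rate = md, freq_diff = fd, concordance = cc,
               pass_maf = checks[["maf"]], pass_hwe = checks[["hwe"]],
               pass_call_rate = checks[["call_rate"]],
               pass_mendel = checks[["mendel"]],
               pass_freq_diff = checks[["freq_diff"]],
               pass_concordance = checks[["concordance"]],
               pass = all(checks, na.rm = TRUE),
               reasons = paste(failed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Polygenic risk score of dopamine-increasing alleles
#'
#' Sums, over variants, the number of copies of each variant's effect
#' (dopamine-increasing) allele. When the effect allele is the counted
#' allele the variant contributes its code; when it is the opposite allele
#' (or the hypothesis is absence of the focal VNTR repeat) it contributes
#' `2 - code`. Individuals missing any included variant get a missing
#' score (complete-case).
#'
#' @param codes matrix or data frame of 0/1/2 codes, individuals in rows,
#'   variants in columns.
#' @param effect_map data frame with columns `variant_id` and `orientation`
#'   (`"counted"` or `"opposite"`), e.g. from [load_effect_alleles()].
#' @return numeric vector of scores in \eqn{[0, 2 \times n_{variants}]},
#'   `NA` for incomplete individuals.
#' @export
risk_score <- function(codes, effect_map) {
  codes <- as.matrix(codes)
  if (!all(c("variant_id", "orientation") %in% names(effect_map)))
    stop("effect_map needs columns variant_id and orientation")
  unmapped <- setdiff(colnames(codes), effect_map$variant_id)
  if (length(unmapped))
    stop("configuration error: no effect-allele mapping for: ",
         paste(unmapped, collapse = ", "))
  ori <- effect_map$orientation[match(colnames(codes), effect_map$variant_id)]
  if (!all(ori %in% c("counted", "opposite")))
    stop("orientation must be \"counted\" or \"opposite\"")
  contrib <- sweep(codes, 2, ifelse(ori == "opposite", 2, 0), function(x, k) {
    abs(k - x)
  })
  score <- rowSums(contrib)
  score[apply(codes, 1, anyNA)] <- NA_real_
  score
}

#' Shipped effect-allele map
#'
#' Reads the packaged mapping from variant to dopamine-increasing effect
#' allele (the allele-specific hypotheses of the study design), expressed
#' relative to each variant's counted allele. The file is a plain CSV and
#' can be replaced by the user via `path`.
#'
#' @param path CSV with columns `variant_id`, `gene`, `counted_allele`,
#'   `effect_allele`, `orientation`, `hypothesis`; defaults to the shipped
#'   table.
#' @return data frame.
#' @export
load_effect_alleles <- function(path = system.file("extdata",
                                                   "effect_alleles.csv",
                                                   package = "twinmet")) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
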