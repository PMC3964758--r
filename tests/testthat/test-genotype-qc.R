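rs4680_spec <- variant_spec("rs4680", "snp", alleles = c("G", "A"),
                            counted_allele = "A", effect_allele = "G",
                            gene = "COMT")
drd4_spec <- variant_spec("DRD4_vntr", "vntr",
                          alleles = as.character(2:11),
                          counted_allele = "7", gene = "DRD4")

test_that("SNP coding counts the designated allele", {
  pairs <- rbind(c("G", "G"), c("G", "A"), c("A", "A"), c(NA, NA))
  expect_equal(as.vector(code_snp(pairs, rs4680_spec)), c(0L, 1L, 2L, NA))
  # brute-force element-count oracle on random pairs
  set.seed(3)
  rp <- matrix(sample(c("G", "A"), 200, replace = TRUE), ncol = 2)
  expect_equal(as.vector(code_snp(rp, rs4680_spec)),
               rowSums(rp == "A"))
  expect_error(code_snp(rbind(c("G", "T")), rs4680_spec), "data error")
})

test_that("VNTR coding counts copies of the focal repeat", {
  pairs <- rbind(c("7", "4"), c("4", "4"), c("7", "7"), c("2", "11"))
  expect_equal(as.vector(code_vntr(pairs, drd4_spec)), c(1L, 0L, 2L, 0L))
  drd5 <- variant_spec("DRD5_vntr", "vntr",
                       alleles = as.character(seq(130, 166, 2)),
                       counted_allele = "148")
  expect_equal(as.vector(code_vntr(rbind(c("148", "148")), drd5)), 2L)
  expect_error(code_vntr(pairs, rs4680_spec), "not a VNTR")
})

test_that("MAF reproduces the published worked examples", {
  # genotype-class counts printed for two candidate variants
  codes_rs1611115 <- rep(0:2, c(137, 1035, 1968))  # TT, TC, CC; C counted
  expect_equal(round(maf(codes_rs1611115), 2), 0.21)
  codes_rs1800497 <- rep(0:2, c(5714, 2684, 358))  # GG, GA, AA; A counted
  expect_equal(round(maf(codes_rs1800497), 2), 0.19)
  expect_equal(maf(rep(1L, 10)), 0.5)
  # folding: invariant to swapping which allele is counted
  set.seed(9)
  g <- sample(0:2, 500, replace = TRUE, prob = c(.5, .4, .1))
  expect_equal(maf(g), maf(2L - g))
  expect_lte(maf(g), 0.5)
  expect_error(maf(c(NA, NA)), "undefined")
  # dosage mode
  expect_equal(maf(c(0.5, 1.5), folded = FALSE), 0.5)
})

test_that("HWE chi-square test reproduces the published p-values", {
  expect_equal(round(hwe_test(c(1968, 1035, 137)), 2), 0.95)
  expect_equal(round(hwe_test(c(2637, 4339, 1779)), 2), 0.94)
  expect_equal(hwe_test(c(25, 50, 25)), 1)     # exact HWE proportions
  expect_equal(hwe_test(c(100, 0, 0)), 1)      # monomorphic convention
  # invariant to exchanging the homozygote classes
  expect_equal(hwe_test(c(30, 40, 10)), hwe_test(c(10, 40, 30)))
  expect_equal(hwe_test(c(30, 40, 10), method = "exact"),
               hwe_test(c(10, 40, 30), method = "exact"))
  # exact and chi-square agree well away from small counts
  expect_lt(abs(hwe_test(c(1968, 1035, 137), method = "exact") -
                  hwe_test(c(1968, 1035, 137))), 0.05)
})

test_that("HWE p-values are calibrated under the null", {
  set.seed(15)
  pvals <- replicate(400, {
    g <- rbinom(1000, 2, 0.3)
    hwe_test(tabulate(factor(g, levels = 0:2), 3))
  })
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 1.96 * sqrt(0.05 * 0.95 / 400) + 0.01)
})

test_that("Mendelian checks flag impossible transmissions only", {
  ped <- toy_trio_ped()
  ids <- c("dad", "mum", "kid1", "kid2")
  g_bad <- stats::setNames(c(0, 0, 2, 0), ids)   # 0/0 parents, code-2 child
  mc <- mendel_check(ped, g_bad)
  expect_equal(mc$errors, 1)
  expect_equal(mc$informative, 2)
  g_het <- stats::setNames(c(1, 1, 0, 2), ids)   # het parents: anything goes
  expect_equal(mendel_check(ped, g_het)$errors, 0)
  # duos: opposite-homozygote parent/child is impossible
  duo <- new_pedigree(data.frame(
    family_id = "F", individual_id = c("p", "q", "c"),
    father_id = c(NA, NA, "p"), mother_id = c(NA, NA, "q"),
    sex = c(1L, 2L, 1L), zygosity = "none", stringsAsFactors = FALSE))
  g_duo <- c(p = 2, q = NA, c = 0)
  expect_equal(mendel_check(duo, g_duo)$errors, 1)
  expect_error(mendel_check(ped, stats::setNames(c(0.3, 1, 1, 1), ids)),
               "hard")
})

test_that("concordance counts identical joint calls", {
  a <- stats::setNames(c(0, 1, 2, NA, 1), paste0("i", 1:5))
  expect_equal(concordance(a, a), 1)
  b <- a; b["i2"] <- 2
  expect_equal(concordance(a, b), 3 / 4)
  expect_equal(concordance(rep(0, 20), c(rep(0, 19), 1)), 0.95)
  # pairwise oracle on random vectors
  set.seed(21)
  for (r in 1:10) {
    x <- sample(c(0:2, NA), 30, replace = TRUE)
    y <- sample(c(0:2, NA), 30, replace = TRUE)
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) next
    expect_equal(concordance(x, y), sum(x[ok] == y[ok]) / sum(ok))
  }
  expect_error(concordance(c(NA, NA), c(1, NA)), "undefined")
})

test_that("QC verdicts match a rule-by-rule re-evaluation", {
  ped <- generate_families(sim_config(n_individuals = 400, seed = 31))
  set.seed(32)
  good <- gene_drop(ped, 0.3, seed = 33)
  rare <- gene_drop(ped, 0.002, seed = 34)              # MAF below threshold
  sparse <- good
  sparse[sample(length(sparse), round(0.1 * length(sparse)))] <- NA  # call rate
  gts <- list(v_good = good, v_rare = rare, v_sparse = sparse)
  th <- qc_thresholds()
  rep_qc <- apply_qc(gts, ped = ped, reference_freqs = c(v_good = 0.30),
                     thresholds = th)
  expect_true(rep_qc$pass[rep_qc$variant_id == "v_good"])
  expect_false(rep_qc$pass[rep_qc$variant_id == "v_rare"])
  expect_match(rep_qc$reasons[rep_qc$variant_id == "v_rare"], "maf")
  expect_false(rep_qc$pass[rep_qc$variant_id == "v_sparse"])
  expect_match(rep_qc$reasons[rep_qc$variant_id == "v_sparse"], "call_rate")
  # independent per-rule oracle
  for (i in seq_len(nrow(rep_qc))) {
    r <- rep_qc[i, ]
    want <- r$maf > th$maf_min && r$hwe_p > th$hwe_p_min &&
      r$call_rate > th$call_rate_min &&
      (is.na(r$mendel_rate) || r$mendel_rate < th$mendel_rate_max) &&
      (is.na(r$freq_diff) || r$freq_diff < th$freq_diff_max)
    expect_identical(r$pass, want)
  }
  # relaxing thresholds never turns a pass into a fail
  lax <- qc_thresholds(hwe_p_min = 0, maf_min = 0, mendel_rate_max = 1,
                       call_rate_min = 0, freq_diff_max = 1,
                       concordance_min = 0)
  rep_lax <- apply_qc(gts, ped = ped, thresholds = lax)
  expect_true(all(rep_lax$pass[rep_qc$pass]))
})

test_that("risk score sums dopamine-increasing allele copies", {
  emap <- load_effect_alleles()
  expect_equal(nrow(emap), 11)
  # homozygous for the effect allele everywhere: code 2 where the effect
  # allele is counted, 0 where it is the opposite allele
  codes_max <- matrix(ifelse(emap$orientation == "counted", 2, 0),
                      nrow = 1, dimnames = list(NULL, emap$variant_id))
  expect_equal(as.vector(risk_score(codes_max, emap)), 22)
  codes_min <- matrix(ifelse(emap$orientation == "counted", 0, 2),
                      nrow = 1, dimnames = list(NULL, emap$variant_id))
  expect_equal(as.vector(risk_score(codes_min, emap)), 0)
  # brute-force per-variant recount on random toy data
  set.seed(41)
  codes <- matrix(sample(0:2, 6 * 11, replace = TRUE), nrow = 6,
                  dimnames = list(NULL, emap$variant_id))
  got <- risk_score(codes, emap)
  want <- apply(codes, 1, function(row) {
    sum(vapply(seq_along(row), function(j) {
      o <- emap$orientation[emap$variant_id == colnames(codes)[j]]
      if (o == "counted") row[j] else 2 - row[j]
    }, numeric(1)))
  })
  expect_equal(unname(got), unname(want))
  expect_true(all(got >= 0 & got <= 22))
  # complete-case: missing any variant -> missing score
  codes[1, 3] <- NA
  expect_true(is.na(risk_score(codes, emap)[1]))
  # unmapped variant is a configuration error
  colnames(codes)[1] <- "rs_unknown"
  expect_error(risk_score(codes, emap), "configuration error")
})
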