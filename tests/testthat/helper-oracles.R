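# Independent oracles and fixture builders, kept deliberately naive so they
# share no code path with the implementation they check.

# recursive path-counting kinship coefficient; A = 2 * phi, with MZ co-twins
# collapsed onto one genetic identity before the recursion
oracle_relationship <- function(ped, id1, id2) {
  df <- as.data.frame(ped)
  rep_of <- stats::setNames(df$individual_id, df$individual_id)
  mz <- df[df$zygosity == "MZ" & !is.na(df$father_id), , drop = FALSE]
  if (nrow(mz)) {
    for (grp in split(mz$individual_id,
                      paste(mz$family_id, mz$father_id, mz$mother_id))) {
      rep_of[grp] <- grp[1]
    }
  }
  fa <- stats::setNames(df$father_id, df$individual_id)
  mo <- stats::setNames(df$mother_id, df$individual_id)
  pos <- stats::setNames(seq_len(nrow(df)), df$individual_id)
  phi <- function(i, j) {
    i <- rep_of[[i]]; j <- rep_of[[j]]
    if (pos[[i]] < pos[[j]]) { tmp <- i; i <- j; j <- tmp }
    # i is now no earlier than j, so i cannot be j's ancestor
    if (i == j) {
      if (is.na(fa[[i]])) return(0.5)
      return(0.5 * (1 + phi(fa[[i]], mo[[i]])))
    }
    if (is.na(fa[[i]])) return(0)
    0.5 * (phi(fa[[i]], j) + phi(mo[[i]], j))
  }
  2 * phi(id1, id2)
}

# explicit multivariate-normal log-likelihood via dense solve
oracle_mvn_loglik <- function(y, X, beta, s2a, s2e, A) {
  V <- s2a * as.matrix(A) + s2e * diag(length(y))
  r <- y - as.matrix(X) %*% beta
  ch <- chol(V)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(forwardsolve(t(ch), r)^2))
}

# GLS beta for fixed variance components
oracle_gls_beta <- function(y, X, s2a, s2e, A) {
  V <- s2a * as.matrix(A) + s2e * diag(length(y))
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# brute-force ML over (s2a, s2e): coarse grid, then two refinement passes
oracle_grid_ml <- function(y, X, A) {
  best <- c(NA, NA, -Inf)
  evaluate <- function(s2a, s2e) {
    b <- oracle_gls_beta(y, X, s2a, s2e, A)
    oracle_mvn_loglik(y, X, b, s2a, s2e, A)
  }
  vy <- stats::var(y)
  s2a_grid <- seq(0, 2 * vy, length.out = 41)
  s2e_grid <- seq(vy / 50, 2 * vy, length.out = 41)
  for (pass in 1:3) {
    for (sa in s2a_grid) for (se in s2e_grid) {
      ll <- evaluate(sa, se)
      if (ll > best[3]) best <- c(sa, se, ll)
    }
    wa <- diff(range(s2a_grid)) / 8
    we <- diff(range(s2e_grid)) / 8
    s2a_grid <- seq(max(0, best[1] - wa), best[1] + wa, length.out = 21)
    s2e_grid <- seq(max(vy / 1e4, best[2] - we), best[2] + we, length.out = 21)
  }
  list(sigma2_a = best[1], sigma2_e = best[2], loglik = best[3])
}

# small hand-built pedigrees ----------------------------------------------

toy_trio_ped <- function(zyg = "none") {
  new_pedigree(data.frame(
    family_id = "FAM1",
    individual_id = c("dad", "mum", "kid1", "kid2"),
    father_id = c(NA, NA, "dad", "dad"),
    mother_id = c(NA, NA, "mum", "mum"),
    sex = c(1L, 2L, 1L, 2L),
    zygosity = c("none", "none", zyg, zyg),
    age = c(48, 47, 20, 20),
    sampled = TRUE, stringsAsFactors = FALSE))
}

# three generations: grandparents -> two parents -> grandchild
toy_three_gen_ped <- function() {
  new_pedigree(data.frame(
    family_id = "G1",
    individual_id = c("gf", "gm", "f", "aunt", "m", "c"),
    father_id = c(NA, NA, "gf", "gf", NA, "f"),
    mother_id = c(NA, NA, "gm", "gm", NA, "m"),
    sex = c(1L, 2L, 1L, 2L, 2L, 1L),
    zygosity = "none",
    sampled = TRUE, stringsAsFactors = FALSE))
}

# pair up co-twins of a generated pedigree with their phenotype values
twin_pairs <- function(ped, y) {
  df <- as.data.frame(ped)
  tw <- df[df$zygosity %in% c("MZ", "DZ"), ]
  tw <- tw[order(tw$family_id, tw$individual_id), ]
  stopifnot(nrow(tw) %% 2 == 0)
  odd <- seq(1, nrow(tw), by = 2)
  data.frame(zyg = tw$zygosity[odd],
             y1 = y[tw$individual_id[odd]],
             y2 = y[tw$individual_id[odd + 1]])
}

# unrelated singletons (A = identity)
singles_ped <- function(n) {
  new_pedigree(data.frame(
    family_id = sprintf("S%03d", seq_len(n)),
    individual_id = sprintf("I%03d", seq_len(n)),
    father_id = NA_character_, mother_id = NA_character_,
    sex = rep(c(1L, 2L), length.out = n), zygosity = "none",
    sampled = TRUE, stringsAsFactors = FALSE))
}
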