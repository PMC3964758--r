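#' Linear mixed model with an additive-genetic random effect
#'
#' Fits \eqn{y = X\beta + a + e} with \eqn{a \sim N(0, \sigma^2_a A)} and
#' \eqn{e \sim N(0, \sigma^2_e I)}, where `A` is the additive genetic
#' relationship matrix, by maximum likelihood (REML optional). The
#' variance ratio \eqn{\lambda = \sigma^2_a/\sigma^2_e} is profiled: after
#' rotating by the family-block eigenvectors of `A` the covariance is
#' diagonal, \eqn{\beta} and \eqn{\sigma^2_e} have closed-form profile
#' maximisers, and a 1-D Brent search over \eqn{\log\lambda} finds the
#' optimum. The boundary \eqn{\sigma^2_a = 0} is evaluated explicitly and
#' reported when it is the maximiser.
#'
#' @param y numeric response (weekly MET hours).
#' @param X design matrix including the intercept column; must be full
#'   rank after complete-case filtering.
#' @param kinship a [kinship_decomp()], a `twin_pedigree`, or a symmetric
#'   relationship matrix aligned with `y`. When `y` has names they are
#'   matched against the decomposition ids.
#' @param method `"ML"` (default, used for all association tests) or
#'   `"REML"`.
#' @return object of class `lmm_fit`: `beta`, `se`, `wald` (per-coefficient
#'   chi-square statistics and p-values), `sigma2_a`, `sigma2_e`, `h2`,
#'   `loglik`, `n_used`, `df_model`, `convergence`, `method`.
#' @export
lmm_fit <- function(y, X, kinship, method = c("ML", "REML")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  keep <- stats::complete.cases(y, X)
  if (sum(keep) < ncol(X) + 2)
    stop("model error: fewer complete cases than fixed effects + 2")
  if (!inherits(kinship, "kinship_decomp")) {
    ids <- if (!is.null(names(y))) names(y)[keep] else NULL
    kinship <- kinship_decomp(kinship, ids = ids)
  } else if (!all(keep)) {
    stop("model error: precomputed decomposition given but data contain ",
         "missing values; filter first")
  }
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  if (!is.null(names(y)) && !is.null(kinship$ids)) {
    if (!all(names(y) %in% kinship$ids))
      stop("model error: response names not covered by the kinship decomposition")
    ord <- match(kinship$ids, names(y))
    ord <- ord[!is.na(ord)]
    if (length(ord) != length(y))
      stop("model error: kinship decomposition and data cover different individuals")
    y <- y[ord]; X <- X[ord, , drop = FALSE]
  }
  if (qr(X)$rank < ncol(X))
    stop("model error: rank-deficient design matrix")
  fit <- lmm_fit_core(y, X, kinship, reml = (method == "REML"))
  fit$method <- method
  fit
}

# core fit on data already aligned with the decomposition
lmm_fit_core <- function(y, X, decomp, reml = FALSE) {
  n <- length(y)
  p <- ncol(X)
  d <- decomp$d
  yt <- as.numeric(Matrix::crossprod(decomp$U, y))
  Xt <- as.matrix(Matrix::crossprod(decomp$U, X))
  dof <- if (reml) n - p else n
  profile <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (1 + lam * d)
    xtwx <- crossprod(Xt, w * Xt)
    xtwy <- crossprod(Xt, w * yt)
    ch <- tryCatch(chol(xtwx), error = function(e) NULL)
    if (is.null(ch)) return(list(nll = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), xtwy))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    s2e <- rss / dof
    ll <- -0.5 * (dof * (log(2 * pi * s2e) + 1) - sum(log(w)))
    if (reml) ll <- ll - 0.5 * (2 * sum(log(diag(ch))) - p * log(s2e))
    list(nll = -ll, beta = beta, s2e = s2e, lam = lam, chol = ch, w = w)
  }
  nll <- function(loglam) profile(loglam)$nll
  opt <- stats::optimize(nll, interval = c(-15, 10), tol = 1e-8)
  at0 <- profile(-Inf)   # lambda = 0 boundary (exp(-Inf) = 0)
  # ties (e.g. A = identity, where the profile is flat) go to the boundary
  boundary <- at0$nll <= opt$objective + 1e-7
  best <- if (boundary) at0 else profile(opt$minimum)
  beta <- drop(best$beta)
  names(beta) <- colnames(X)
  cov_beta <- best$s2e * chol2inv(best$chol)
  se <- sqrt(diag(cov_beta))
  names(se) <- colnames(X)
  wald_stat <- (beta / se)^2
  wald_p <- stats::pchisq(wald_stat, df = 1, lower.tail = FALSE)
  sigma2_e <- best$s2e
  sigma2_a <- best$lam * sigma2_e
  if (boundary) sigma2_a <- 0
  structure(list(
    beta = beta, se = se, cov_beta = cov_beta,
    wald = data.frame(coefficient = colnames(X), statistic = wald_stat,
                      p_value = wald_p, row.names = NULL,
                      stringsAsFactors = FALSE),
    sigma2_a = sigma2_a, sigma2_e = sigma2_e,
    h2 = sigma2_a / (sigma2_a + sigma2_e),
    loglik = -best$nll, n_used = n, df_model = ncol(X),
    convergence = TRUE, boundary = boundary), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), n = %d\n", x$method, x$n_used))
  tab <- data.frame(estimate = x$beta, se = x$se,
                    wald = x$wald$statistic, p = x$wald$p_value)
  print(round(tab, 4))
  cat(sprintf("sigma2_a = %.4f%s, sigma2_e = %.4f, h2 = %.3f, loglik = %.4f\n",
              x$sigma2_a, if (x$boundary) " (boundary)" else "",
              x$sigma2_e, x$h2, x$loglik))
  invisible(x)
}

#' Wald test of a single coefficient
#'
#' Two-sided Wald chi-square test, \eqn{(\hat\beta/SE)^2} against
#' \eqn{\chi^2_1}, with a significance verdict at the supplied alpha
#' (typically the Bonferroni-corrected level).
#'
#' @param fit an [lmm_fit()] result.
#' @param coefficient name of the fixed effect to test.
#' @param alpha significance level (default .05/11).
#' @return list of class `twinmet_test`: `statistic`, `df`, `p_value`,
#'   `alpha_used`, `significant`.
#' @export
test_variant <- function(fit, coefficient, alpha = bonferroni_alpha(0.05, 11)) {
  stopifnot(inherits(fit, "lmm_fit"))
  i <- match(coefficient, names(fit$beta))
  if (is.na(i)) stop("coefficient not in fit: ", coefficient)
  stat <- unname((fit$beta[i] / fit$se[i])^2)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(statistic = stat, df = 1L, p_value = p, alpha_used = alpha,
                 significant = p < alpha, coefficient = coefficient,
                 type = "Wald"), class = "twinmet_test")
}

#' Likelihood-ratio test of nested mixed models
#'
#' Chi-square statistic \eqn{2(\ell_{full} - \ell_{null})} with degrees of
#' freedom equal to the number of added fixed-effect terms, for a joint
#' test of several variants included in a single model. Both fits must be
#' maximum-likelihood fits on the same complete-case sample, with the null
#' model's fixed effects a subset of the full model's.
#'
#' @param full_fit,null_fit nested [lmm_fit()] results.
#' @param alpha significance level.
#' @return list of class `twinmet_test`.
#' @export
joint_test <- function(full_fit, null_fit, alpha = bonferroni_alpha(0.05, 11)) {
  stopifnot(inherits(full_fit, "lmm_fit"), inherits(null_fit, "lmm_fit"))
  if (full_fit$n_used != null_fit$n_used)
    stop("model error: fits use different complete-case samples")
  if (!all(names(null_fit$beta) %in% names(full_fit$beta)))
    stop("model error: null model is not nested in the full model")
  if (!is.null(full_fit$method) && !is.null(null_fit$method) &&
      (full_fit$method != "ML" || null_fit$method != "ML"))
    stop("model error: likelihood-ratio tests require ML fits")
  df <- full_fit$df_model - null_fit$df_model
  stat <- max(0, 2 * (full_fit$loglik - null_fit$loglik))
  # identical models are a degenerate but valid case: statistic 0, p = 1
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p, alpha_used = alpha,
                 significant = p < alpha, type = "LRT"),
            class = "twinmet_test")
}

#' @export
print.twinmet_test <- function(x, ...) {
  cat(sprintf("%s test: chi-square = %.4f, df = %d, p = %.4g (alpha = %.4g)%s\n",
              x$type, x$statistic, x$df, x$p_value, x$alpha_used,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Bonferroni-corrected alpha level
#'
#' @param family_alpha family-wise error rate (e.g. .05).
#' @param n_tests number of tests (e.g. 11 variants).
#' @return per-test alpha `family_alpha / n_tests`.
#' @export
bonferroni_alpha <- function(family_alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  if (family_alpha <= 0 || family_alpha >= 1)
    stop("family_alpha must lie in (0, 1)")
  family_alpha / n_tests
}

#' Standardize ages to z-scores
#'
#' Centers and scales by the analysis-sample mean and SD (n-1 denominator).
#'
#' @param ages numeric vector with at least two distinct values.
#' @return z-scores with mean 0 and SD 1.
#' @export
standardize_age <- function(ages) {
  ok <- ages[!is.na(ages)]
  if (length(unique(ok)) < 2) stop("need at least two distinct ages")
  (ages - mean(ok)) / stats::sd(ok)
}

#' Single-variant association test on an analysis table
#'
#' Convenience wrapper reproducing the study's single-variant model:
#' weekly MET hours regressed on sex (0 = male, 1 = female), standardized
#' age, their interaction and the variant code, with an additive-genetic
#' random effect over the family relationship matrix. Complete cases for
#' the involved columns are used and `n_used` is reported.
#'
#' @param data data frame with columns `individual_id`, `met_hours`,
#'   `sex` (0/1), `age`, and one column per variant code; extra covariate
#'   columns may be named in `covariates`.
#' @param ped a `twin_pedigree` covering the individuals.
#' @param variant name(s) of variant code column(s) to include; all are
#'   added jointly.
#' @param covariates optional extra fixed-effect column names.
#' @param include_sex_age include sex, age_z and sex x age_z (default
#'   `TRUE`; the power simulations set this to `FALSE`).
#' @param alpha significance level for the variant test.
#' @return list with `fit` (the full [lmm_fit()]), `null_fit`, `test` (Wald
#'   for one variant, LRT for several) and `n_used`.
#' @export
met_assoc <- function(data, ped, variant, covariates = character(0),
                      include_sex_age = TRUE,
                      alpha = bonferroni_alpha(0.05, 11)) {
  needed <- c("individual_id", "met_hours", variant, covariates,
              if (include_sex_age) c("sex", "age"))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("data are missing columns: ", paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(data[needed])
  d <- data[cc, , drop = FALSE]
  X0 <- cbind(`(Intercept)` = rep(1, nrow(d)))
  if (include_sex_age) {
    age_z <- standardize_age(d$age)
    X0 <- cbind(X0, sex = d$sex, age_z = age_z, `sex:age_z` = d$sex * age_z)
  }
  for (cv in covariates) X0 <- cbind(X0, stats::setNames(d[cv], cv))
  X0 <- as.matrix(X0)
  Xv <- as.matrix(d[variant])
  decomp <- kinship_decomp(ped, ids = d$individual_id)
  y <- stats::setNames(d$met_hours, d$individual_id)
  ord <- match(decomp$ids, d$individual_id)
  full <- lmm_fit_core(y[ord], cbind(X0, Xv)[ord, , drop = FALSE], decomp)
  full$method <- "ML"
  if (length(variant) == 1L) {
    test <- test_variant(full, variant, alpha)
    null_fit <- NULL
  } else {
    null_fit <- lmm_fit_core(y[ord], X0[ord, , drop = FALSE], decomp)
    null_fit$method <- "ML"
    test <- joint_test(full, null_fit, alpha)
  }
  list(fit = full, null_fit = null_fit, test = test, n_used = nrow(d))
}
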