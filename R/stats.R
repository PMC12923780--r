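#' Cohen's d from group summary statistics
#'
#' Standardised mean difference using the average-variance denominator
#' `sqrt((sd1^2 + sd2^2)/2)`. This pooling (rather than the n-weighted
#' pooled SD) is the convention that reproduces the reference cohort's
#' published effect sizes from its printed means and SDs.
#'
#' @param mean1,sd1 Summary statistics of the first group.
#' @param mean2,sd2 Summary statistics of the second group.
#' @return Signed effect size d; the sign follows the argument order.
#' @examples
#' cohens_d(7.04, 1.3, 5.3, 0.4)  # ~1.81
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (sd1 < 0 || sd2 < 0) stopf("SDs must be non-negative")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(0)
    stopf("both SDs are zero with unequal means: effect size is infinite")
  }
  (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Cohen's f from Cohen's d
#'
#' The f = |d| / 2 convention for two-group comparisons.
#'
#' @param d Cohen's d (any sign).
#' @return Non-negative effect size f.
#' @export
cohens_f <- function(d) abs(d) / 2

#' Independent two-sample t-test
#'
#' Two-sided independent-samples t-test; Student's equal-variance form by
#' default (matching common statistical-package output), Welch optional.
#'
#' @param x,y Numeric samples (n >= 2 each; NAs dropped).
#' @param equal_variance Use the pooled-variance Student test (default).
#' @return List with `t`, `df`, `p`.
#' @export
independent_t_test <- function(x, y, equal_variance = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stopf("each sample needs n >= 2")
  if (stats::var(x) + stats::var(y) == 0) {
    stopf("both samples have zero variance; t is undefined")
  }
  ht <- stats::t.test(x, y, var.equal = equal_variance)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction.
#'
#' @param contingency Matrix of non-negative counts, at least 2 x 2.
#' @return List with `statistic`, `df`, `p`.
#' @examples
#' chi_square_test(matrix(c(39, 53, 39, 53), nrow = 2))  # p = 1
#' @export
chi_square_test <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (nrow(contingency) < 2 || ncol(contingency) < 2) {
    stopf("contingency table must be at least 2 x 2")
  }
  if (any(contingency < 0) || any(contingency != round(contingency))) {
    stopf("contingency table must hold non-negative integer counts")
  }
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stopf("contingency table has a zero marginal")
  }
  ht <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' ANCOVA test of a group effect
#'
#' Ordinary least squares of the outcome on a group indicator plus
#' covariates; the group effect is tested by the partial t (equivalently the
#' partial F) for the group term. With no covariates this reduces exactly to
#' the equal-variance two-sample t-test.
#'
#' @param outcome Numeric outcome per subject.
#' @param group Two-level factor/character/indicator per subject.
#' @param covariates Optional data frame of numeric or binary-coded
#'   covariates (sex is coded female = 0, male = 1 by
#'   [binarize_covariates()]). Rows with missing values are dropped
#'   analysis-wise.
#' @return List with `p`, `t`, `df`, `n`, `estimate` (adjusted group
#'   difference, first level minus second), `model` (the `lm` fit).
#' @export
ancova_group_test <- function(outcome, group, covariates = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stopf("`group` must have exactly two levels")
  df <- data.frame(.outcome = outcome, .group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(outcome))
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) <= ncol(df) + 1L) {
    stopf("too few complete cases (%d) for the model terms", nrow(df))
  }
  X <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stopf("collinear ANCOVA design; aliased columns: %s",
          paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(.outcome ~ ., data = df)
  sm <- summary(fit)$coefficients
  grow <- grep("^\\.group", rownames(sm))
  list(
    p = sm[grow, "Pr(>|t|)"],
    t = sm[grow, "t value"],
    df = fit$df.residual,
    n = nrow(df),
    estimate = -sm[grow, "Estimate"],  # first level minus second
    model = fit
  )
}

#' Binary-code cognitive, sleepiness and OSA covariates
#'
#' Codes MoCA as 1 when total score < 26 (cognitive impairment) else 0, ESS
#' as 1 when score >= 11 (excessive daytime sleepiness) else 0, sex as
#' male = 1 / female = 0, and passes OSA through as 0/1. Missing values stay
#' missing.
#'
#' @param records Data frame with any of `moca`, `ess`, `sex`, `osa`.
#' @return The data frame with added `moca_low`, `ess_high`, `sex_male`
#'   columns (where the inputs exist).
#' @export
binarize_covariates <- function(records) {
  if ("moca" %in% names(records)) {
    records$moca_low <- ifelse(is.na(records$moca), NA_integer_,
                               as.integer(records$moca < 26))
  }
  if ("ess" %in% names(records)) {
    records$ess_high <- ifelse(is.na(records$ess), NA_integer_,
                               as.integer(records$ess >= 11))
  }
  if ("sex" %in% names(records)) {
    records$sex_male <- ifelse(is.na(records$sex), NA_integer_,
                               as.integer(records$sex == "male"))
  }
  if ("osa" %in% names(records)) {
    records$osa <- as.integer(records$osa)
  }
  records
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)`, preserving order. The family size `m` defaults
#' to the number of p-values but may be set explicitly when the tested
#' family is larger than the vector supplied.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param m Family size (>= 1).
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  if (!is_scalar_num(m) || m < 1) stopf("`m` must be a positive integer")
  pmin(1, p * m)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors (pairwise-complete, n >= 3).
#' @return List with `r`, `p`, `n`, `df`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need n >= 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stopf("zero variance; correlation undefined")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value),
       n = length(x), df = unname(ht$parameter))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after each is
#' regressed (OLS) on the covariates; the p-value uses the t transform with
#' degrees of freedom reduced by the number of covariates. With an empty
#' covariate set this is exactly the Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame (or NULL/empty for plain Pearson).
#' @return List with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(pearson_correlation(x, y))
  }
  covariates <- as.data.frame(covariates)
  ok <- stats::complete.cases(x, y, covariates)
  x <- x[ok]; y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  k <- ncol(covariates)
  n <- length(x)
  if (n <= k + 2) stopf("need n > %d for %d covariates", k + 2, k)
  Z <- stats::model.matrix(~ ., data = covariates)
  if (qr(Z)$rank < ncol(Z)) stopf("collinear covariates in partial correlation")
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stopf("zero residual variance; partial correlation undefined")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), n = n, df = df)
}
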