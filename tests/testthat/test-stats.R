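test_that("cohens_d with average-variance pooling reproduces published table values", {
  printed <- list(
    # mean1, sd1, mean2, sd2, expected d (2 dp)
    hba1c  = c(7.04, 1.3, 5.3, 0.4, 1.81),
    age    = c(56.5, 7.5, 54.7, 6.5, 0.26),
    bmi    = c(29.45, 5.0, 26.28, 4.2, 0.69),
    hr     = c(77.3, 11.8, 71.7, 10.9, 0.49),
    sbp    = c(127.8, 15.3, 120.7, 17.2, 0.44),
    dbp    = c(78.6, 10.4, 78.8, 14.2, -0.02),
    ess    = c(6.7, 3.9, 5.1, 3.3, 0.44),
    moca   = c(25.9, 2.5, 27.1, 2.3, -0.50)
  )
  for (v in printed) {
    expect_equal(round(cohens_d(v[1], v[2], v[3], v[4]), 2), v[5])
  }
  expect_equal(cohens_d(3, 1.2, 3, 1.2), 0)
  expect_error(cohens_d(1, 0, 2, 0), "infinite")
})

test_that("cohens_f = |d|/2 reproduces the published diffusivity effect sizes", {
  expect_equal(round(cohens_f(cohens_d(1.296, 0.11, 1.35, 0.11)), 2), 0.25)
  expect_equal(round(cohens_f(cohens_d(0.50, 0.05, 0.47, 0.05)), 1), 0.3)
  expect_equal(round(cohens_f(cohens_d(0.04, 0.01, 0.05, 0.01)), 1), 0.5)
  expect_equal(round(cohens_f(cohens_d(0.61, 0.06, 0.59, 0.06)), 2), 0.17)
  expect_equal(round(cohens_f(cohens_d(0.08, 0.03, 0.09, 0.03)), 2), 0.17)
  expect_equal(cohens_f(0), 0)
})

test_that("independent t-test matches the hand-computed pooled statistic", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  ht <- independent_t_test(x, y, equal_variance = TRUE)
  # pooled sd = 1, se = sqrt(2/3), t = -3 / se
  expect_equal(ht$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ht$df, 4)
  expect_equal(ht$p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(round(ht$p, 4), 0.0213)

  swapped <- independent_t_test(y, x)
  expect_equal(swapped$t, -ht$t)
  expect_equal(swapped$p, ht$p)

  same <- independent_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(independent_t_test(c(1, 1), c(1, 1)), "zero variance")
})

test_that("chi-square test handles the published sex table and closed forms", {
  sex <- matrix(c(39, 53, 39, 53), nrow = 2)   # rows = groups
  ht <- chi_square_test(sex)
  expect_equal(ht$statistic, 0)
  expect_equal(ht$p, 1)

  diagonal <- matrix(c(10, 0, 0, 10), nrow = 2)
  ht2 <- chi_square_test(diagonal)
  expect_equal(ht2$statistic, 20)
  expect_equal(ht2$df, 1)

  proportional <- matrix(c(10, 20, 30, 60), nrow = 2)
  expect_equal(chi_square_test(proportional)$statistic, 0)

  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), nrow = 2)),
               "marginal")
})

test_that("ANCOVA without covariates equals the equal-variance t-test", {
  set.seed(14)
  outcome <- c(rnorm(20, 1.30, 0.1), rnorm(25, 1.35, 0.1))
  group <- rep(c("T2DM", "control"), c(20, 25))
  anc <- ancova_group_test(outcome, group)
  tt <- independent_t_test(outcome[group == "T2DM"],
                           outcome[group == "control"])
  expect_equal(anc$p, tt$p, tolerance = 1e-12)
  expect_equal(anc$t^2, tt$t^2, tolerance = 1e-12)
})

test_that("ANCOVA matches an explicit normal-equations oracle", {
  # 8-subject worked example with one covariate
  y <- c(1.25, 1.31, 1.22, 1.28, 1.36, 1.41, 1.33, 1.38)
  grp <- rep(c(1, 0), each = 4)          # 1 = patient
  age <- c(61, 55, 63, 58, 52, 49, 57, 54)
  anc <- ancova_group_test(y, factor(grp, levels = c(1, 0)),
                           data.frame(age = age))

  X <- cbind(1, as.numeric(grp == 0), age)  # second factor level dummy
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (8 - 3)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tval <- beta[2] / se
  expect_equal(abs(anc$t), abs(tval), tolerance = 1e-10)
  expect_equal(anc$p, 2 * pt(-abs(tval), 5), tolerance = 1e-12)
})

test_that("collinear ANCOVA designs raise an informative error", {
  y <- rnorm(10)
  grp <- rep(c("a", "b"), 5)
  expect_error(
    ancova_group_test(y, grp, data.frame(dup = as.integer(grp == "b"))),
    "collinear|aliased"
  )
})

test_that("covariate binarisation applies the exact thresholds", {
  rec <- data.frame(
    moca = c(25, 26, NA, 21), ess = c(11, 10, 24, NA),
    sex = c("male", "female", NA, "male"), osa = c(0, 1, 0, NA)
  )
  coded <- binarize_covariates(rec)
  expect_equal(coded$moca_low, c(1L, 0L, NA, 1L))
  expect_equal(coded$ess_high, c(1L, 0L, 1L, NA))
  expect_equal(coded$sex_male, c(1L, 0L, NA, 1L))
  expect_equal(coded$osa, c(0L, 1L, 0L, NA))
})

test_that("Bonferroni adjustment scales, caps, and never decreases", {
  expect_equal(bonferroni_adjust(0.01, m = 1), 0.01)
  expect_equal(bonferroni_adjust(c(0.4, 0.01), m = 3), c(1.0, 0.03))
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(2:15, 1))
    adj <- bonferroni_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(adj, p.adjust(p, method = "bonferroni"))
  }
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Pearson correlation matches hand-computed values", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1)
  ht <- pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(ht$r, 0.8)   # covariance 4 / (sd 5 * sd 5) by hand
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("partial correlation reduces to, and deviates from, Pearson correctly", {
  set.seed(4)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)

  # empty covariate set: identical to Pearson, bit for bit
  expect_identical(partial_correlation(x, y, NULL), pearson_correlation(x, y))
  expect_identical(partial_correlation(x, y, data.frame()),
                   pearson_correlation(x, y))

  # covariate exactly orthogonal to both: r unchanged within 1e-12
  z <- rnorm(40)
  z <- z - qr.fitted(qr(cbind(1, x, y)), z)   # orthogonalise to x, y, 1
  pr <- partial_correlation(x, y, data.frame(z = z))
  expect_equal(pr$r, pearson_correlation(x, y)$r, tolerance = 1e-12)
  expect_equal(pr$df, 40 - 3)

  # shared driver removed: residual correlation near zero at large n
  n <- 5000
  set.seed(5)
  c0 <- rnorm(n)
  a <- c0 + rnorm(n); b <- c0 + rnorm(n)
  pr2 <- partial_correlation(a, b, data.frame(c0 = c0))
  expect_lt(abs(pr2$r), 3 / sqrt(n))
  expect_gt(pearson_correlation(a, b)$r, 0.4)
})
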