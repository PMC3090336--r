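test_that("2x2 chi-square reproduces the pooled filter comparisons", {
  # pooled call-rate counts: 245/300 without flank constraints vs
  # 365/396 with them
  res <- pearson_chi2_2x2(matrix(c(245, 55, 365, 31), 2, byrow = TRUE))
  expect_lt(abs(res$statistic - 17.40), 0.01)
  expect_lt(res$p_value, 1e-4)
  # pooled polymorphism counts at MAF >= 0.05
  res2 <- pearson_chi2_2x2(matrix(c(178, 122, 279, 117), 2,
                                  byrow = TRUE))
  expect_equal(round(res2$statistic, 2), 9.36)
  expect_equal(round(res2$p_value, 5), 0.00221)

  expect_equal(pearson_chi2_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_true(is.na(pearson_chi2_2x2(
    matrix(c(5, 0, 7, 0), 2))$statistic))
})

test_that("chi-square is invariant under row and column swaps", {
  set.seed(14)
  for (i in 1:20) {
    m <- matrix(sample(1:80, 4), 2)
    s0 <- pearson_chi2_2x2(m)$statistic
    expect_equal(pearson_chi2_2x2(m[2:1, ])$statistic, s0)
    expect_equal(pearson_chi2_2x2(m[, 2:1])$statistic, s0)
    expect_equal(pearson_chi2_2x2(t(m))$statistic, s0)
  }
})

test_that("chi-square keeps its nominal type-I error on null tables", {
  set.seed(15)
  rej <- vapply(1:2000, function(i) {
    a <- rbinom(1, 300, 0.8); b <- rbinom(1, 396, 0.8)
    p <- pearson_chi2_2x2(matrix(c(a, 300 - a, b, 396 - b), 2,
                                 byrow = TRUE))$p_value
    !is.na(p) && p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("Mann-Whitney handles separation, identity and exactness", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.95)

  # exact p equals the independent wilcox.test enumeration (no ties)
  set.seed(16)
  for (i in 1:10) {
    x <- sample(1:1000, 5); y <- sample(1:1000, 5) + 0.5  # no ties
    ours <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$method, "exact enumeration")
  }

  # large samples: normal approximation close to wilcox.test's
  x <- rnorm(30); y <- rnorm(30, 0.5)
  ours <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("two-sided exact binomial doubles the smaller tail", {
  expect_equal(exact_binomial_two_sided(0L, 5L), 0.0625)
  expect_equal(exact_binomial_two_sided(2L, 5L), 1.0)  # capped
  expect_equal(exact_binomial_two_sided(4L, 8L), 1.0)  # symmetric centre
  # enumeration oracle over n = 5..20 and all k
  for (n in 5:20) {
    mass <- dbinom(0:n, n, 0.5)
    for (k in 0:n) {
      expected <- min(1, 2 * min(sum(mass[1:(k + 1)]),
                                 sum(mass[(k + 1):(n + 1)])))
      expect_equal(exact_binomial_two_sided(k, n), expected,
                   tolerance = 1e-12)
      expect_equal(exact_binomial_two_sided(k, n),
                   exact_binomial_two_sided(n - k, n))
    }
  }
  expect_error(exact_binomial_two_sided(0L, 0L), "n must be")
})

test_that("MAF sample-size calculation matches the normal formula", {
  res <- min_sample_size_for_maf(0.05, 0.025, 0.95)
  expect_equal(res$n_alleles, 292L)
  expect_equal(res$n_individuals, 146L)
  expect_equal(min_sample_size_for_maf(0.5, 0.5, 0.95)$n_alleles, 4L)
  # halving the halfwidth quadruples n (within ceiling effects)
  n1 <- min_sample_size_for_maf(0.2, 0.05)$n_alleles
  n2 <- min_sample_size_for_maf(0.2, 0.025)$n_alleles
  expect_lte(abs(n2 - 4L * n1), 4L)
})

test_that("logistic IRLS maximises the likelihood", {
  # 6-point dataset: compare against a brute-force grid maximisation
  x <- c(-2, -1, 0, 0.5, 1, 2)
  y <- c(0, 0, 1, 0, 1, 1)
  fit <- logistic_fit(y, matrix(x, ncol = 1))
  ll_grid <- function(b0s, b1s) {
    # vectorised log-likelihood over the whole grid
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    eta <- outer(x, grid$b1) + rep(grid$b0, each = length(x))
    mu <- 1 / (1 + exp(-eta))
    grid$ll <- colSums(y * log(mu) + (1 - y) * log(1 - mu))
    grid[which.max(grid$ll), ]
  }
  coarse <- ll_grid(seq(-3, 3, by = 0.02), seq(0, 5, by = 0.02))
  best <- ll_grid(seq(coarse$b0 - 0.03, coarse$b0 + 0.03, by = 0.001),
                  seq(coarse$b1 - 0.03, coarse$b1 + 0.03, by = 0.001))
  expect_equal(unname(fit$coefficients[1]), best$b0, tolerance = 2e-3)
  expect_equal(unname(fit$coefficients[2]), best$b1, tolerance = 2e-3)
  expect_true(fit$converged)

  # cross-check against the installed GLM fitter on a larger problem
  set.seed(17)
  xx <- cbind(a = rnorm(200), b = rnorm(200))
  yy <- rbinom(200, 1, 1 / (1 + exp(-(0.5 + xx[, 1] - 0.7 * xx[, 2]))))
  ours <- logistic_fit(yy, xx)
  ref <- stats::glm(yy ~ xx, family = stats::binomial())
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(ours$deviance), ref$deviance, tolerance = 1e-6)
})

test_that("logistic fit flags separation and collinearity", {
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fit <- logistic_fit(y, matrix(y, ncol = 1)),
                 "separation")
  expect_true(fit$separated)
  x <- cbind(a = 1:6, b = 2 * (1:6))
  expect_error(logistic_fit(y, x), "b")
})

test_that("logistic slope CI covers zero under the null", {
  set.seed(18)
  cover <- vapply(1:100, function(i) {
    x <- rnorm(200)
    y <- rbinom(200, 1, 0.4)      # independent of x
    fit <- logistic_fit(y, matrix(x, ncol = 1))
    b <- fit$coefficients[2]; s <- fit$se[2]
    b - 1.96 * s < 0 && 0 < b + 1.96 * s
  }, logical(1))
  expect_gte(sum(cover), 93L)
})
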