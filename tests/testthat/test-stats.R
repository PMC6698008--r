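test_that("chi-square: independence gives zero statistic, bad tables error", {
  r <- pearson_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margins")
  expect_error(pearson_chi2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("chi-square p agrees with a permutation null on a random 2x2 table", {
  set.seed(14)
  g <- rbinom(200, 1, 0.5); y <- rbinom(200, 1, 0.4)
  tab <- table(g, y)
  obs <- pearson_chi2(tab)
  stat <- function(g, y) {
    t <- table(g, y)
    e <- outer(rowSums(t), colSums(t)) / sum(t)
    sum((t - e)^2 / e)
  }
  perm <- replicate(20000, stat(sample(g), y))
  # the permutation null is discrete: compare the continuous chi-square p
  # against the permutation mid-p (half the atom at the observed value)
  p_perm <- mean(perm > obs$chi2 + 1e-9) +
    mean(abs(perm - obs$chi2) <= 1e-9) / 2
  expect_lt(abs(p_perm - obs$p), 3 * sqrt(p_perm * (1 - p_perm) / 20000) + 0.02)
})

test_that("t-test and Mann-Whitney behave on symmetric and separated samples", {
  x <- c(1, 2, 3, 4, 5)
  r <- ttest_ind(x, x)
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  expect_error(ttest_ind(c(1, 1), c(1, 1)), "zero variance")

  mw <- mann_whitney(x, x, exact = FALSE)
  expect_equal(mw$U, length(x)^2 / 2)
  expect_equal(mw$p, 1)

  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw_u <- sep$U, 0)
  expect_equal(sep$p, 0.1) # exact two-sided p from the 20 rank assignments
})

test_that("t-test p-values are uniform under the null", {
  set.seed(77)
  ps <- replicate(400, ttest_ind(rnorm(50), rnorm(50))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Lilliefors-corrected KS flags non-normal but passes normal samples", {
  set.seed(5)
  expect_gt(ks_normality(rnorm(200))$p, 0.01)
  expect_lt(ks_normality(rexp(200))$p, 0.001)
  expect_error(ks_normality(c(1, 2)), ">= 5")
})

test_that("Spearman: monotone sequences and midrank ties", {
  x <- 1:10
  expect_equal(spearman_cor(x, x + 3)$rho, 1)
  expect_equal(spearman_cor(x, -2 * x)$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")

  set.seed(3)
  xt <- sample(rep(1:4, times = c(3, 3, 2, 2)))
  yt <- sample(rep(1:3, times = c(4, 3, 3)))
  r <- spearman_cor(xt, yt)
  expect_equal(r$rho, unname(cor(rank(xt), rank(yt)))) # midrank oracle
})

test_that("TMA score aggregation averages scored cores only", {
  expect_equal(aggregate_tma_scores(rep(2, 6)), 2)
  expect_true(is.na(aggregate_tma_scores(rep(NA_real_, 6))))
  expect_equal(aggregate_tma_scores(c(0, 1, 3, NA, NA, NA)), 4 / 3)
  expect_error(aggregate_tma_scores(c(1, 5)), "0, 1, 2, 3")
  expect_error(aggregate_tma_scores(rep(1, 7)), "at most 6")
})

test_that("Youden cutoff: perfect separation and degenerate two-value case", {
  r <- dichotomize_roc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_gt(r$cutoff, 3); expect_lt(r$cutoff, 10)
  expect_equal(r$youden_j, 1)
  expect_equal(r$direction, "high_positive")

  # two distinct values carrying no signal: the single midpoint, J = 0
  r0 <- dichotomize_roc(c(1, 1, 2, 2), c(0, 1, 0, 1))
  expect_equal(r0$cutoff, 1.5)
  expect_equal(r0$youden_j, 0)

  expect_error(dichotomize_roc(c(1, 2, 3), c(1, 1, 1)), "both outcome")
  expect_error(dichotomize_roc(c(2, 2, 2), c(0, 1, 0)), "distinct")
})

test_that("Youden cutoff equals the exhaustive scan oracle on random data", {
  set.seed(101)
  for (i in 1:25) {
    v <- round(rnorm(50), 2)
    y <- rbinom(50, 1, plogis(v * runif(1, -2, 2)))
    if (length(unique(y)) < 2 || length(unique(v)) < 2) next
    got <- dichotomize_roc(v, y)
    ref <- youden_oracle(v, y)
    expect_equal(got$youden_j, ref$j, tolerance = 1e-10)
    expect_equal(got$cutoff, ref$cutoff)
  }
})

test_that("Youden J agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  v <- rnorm(80); y <- rbinom(80, 1, plogis(1.2 * v))
  got <- dichotomize_roc(v, y)
  roc <- pROC::roc(y, v, quiet = TRUE, direction = "<")
  best <- max(roc$sensitivities + roc$specificities - 1)
  expect_equal(got$youden_j, best, tolerance = 1e-10)
})
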