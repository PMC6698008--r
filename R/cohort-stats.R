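#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic `sum((O - E)^2 / E)` without continuity correction,
#' with `df = (r - 1)(k - 1)` and a two-sided p-value from the chi-square
#' distribution. The uncorrected statistic is the one that reproduces the
#' printed baseline-table p-values this package validates against.
#'
#' @param table integer matrix of counts (2 x k or r x k).
#' @return an object of class `contingency_result`: `chi2`, `df`, `p`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate margins: all-zero row or column")
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  structure(list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Independent two-sample t-test (pooled variance)
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return list with `t`, `df`, `p`.
#' @export
ttest_ind <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per sample")
  if (sd(x) == 0 && sd(y) == 0) stop("zero variance in both samples")
  ht <- t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U. Exact when both samples are small and
#' tie-free, otherwise the normal approximation with tie correction (no
#' continuity correction). The reported `U` counts pairs in which the
#' first sample precedes the second.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @param exact force (`TRUE`)/suppress (`FALSE`) the exact distribution;
#'   `NULL` chooses automatically.
#' @return list with `U`, `p`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per sample")
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Kolmogorov-Smirnov normality test (Lilliefors correction)
#'
#' Tests a sample against the normal family with mean and standard
#' deviation estimated from the sample, using the Lilliefors-corrected
#' null distribution of the KS statistic.
#'
#' @param x numeric sample, at least 5 observations.
#' @return list with `D`, `p`.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5) stop("need >= 5 observations")
  ht <- nortest::lillie.test(x)
  list(D = unname(ht$statistic), p = ht$p.value)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties; two-sided p-value via the
#' t approximation.
#'
#' @param x,y paired numeric vectors; pairs with missing values dropped.
#' @return an object of class `correlation_result`: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant input: correlation undefined")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  structure(list(rho = unname(ht$estimate), p = ht$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, p = %.4g)\n", x$rho, x$n, x$p))
  invisible(x)
}

#' Aggregate tissue-microarray core scores
#'
#' Per-patient TMA score: the mean of up to six ordinal core intensity
#' scores (0 = negative, 1 = weak, 2 = moderate, 3 = strong). Damaged or
#' missing cores (`NA`) are ignored; a patient with no scored cores gets
#' `NA`.
#'
#' @param core_scores numeric vector, length <= 6, values in `{0,1,2,3}`
#'   or `NA`.
#' @return the mean score, or `NA_real_`.
#' @export
aggregate_tma_scores <- function(core_scores) {
  if (length(core_scores) > 6) stop("at most 6 cores per patient")
  v <- core_scores[!is.na(core_scores)]
  if (any(!(v %in% 0:3))) stop("core scores must lie in {0, 1, 2, 3}")
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Dichotomize a continuous marker by ROC / Youden's J
#'
#' Evaluates every midpoint between consecutive sorted distinct marker
#' values as a candidate cutoff and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1. The "high" group is strictly greater
#' than the cutoff. Ties are broken toward the smallest cutoff. With
#' `direction = "auto"` the orientation (high values predict the outcome,
#' or low values do) is chosen to maximize J.
#'
#' @param values continuous marker values.
#' @param outcome binary outcome (0/1) aligned with `values`.
#' @param direction `"auto"`, `"high_positive"` or `"low_positive"`.
#' @return an object of class `cutoff_result`: `cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`, `direction`.
#' @export
dichotomize_roc <- function(values, outcome,
                            direction = c("auto", "high_positive",
                                          "low_positive")) {
  direction <- match.arg(direction)
  ok <- !is.na(values) & !is.na(outcome)
  values <- values[ok]; outcome <- outcome[ok]
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(values)) < 2) stop("need >= 2 distinct marker values")
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  u <- sort(unique(values))
  cuts <- (u[-length(u)] + u[-1]) / 2
  sens_high <- vapply(cuts, function(c) mean(values[outcome == 1] > c), 0)
  spec_high <- vapply(cuts, function(c) mean(values[outcome == 0] <= c), 0)
  j_high <- sens_high + spec_high - 1
  pick <- function(j) which(j >= max(j) - 1e-12)[1] # smallest cutoff on ties
  if (direction == "auto")
    direction <- if (max(j_high) >= max(-j_high) - 1e-12)
      "high_positive" else "low_positive"
  if (direction == "high_positive") {
    i <- pick(j_high)
    res <- list(cutoff = cuts[i], sensitivity = sens_high[i],
                specificity = spec_high[i], youden_j = j_high[i],
                direction = "high_positive")
  } else {
    j_low <- -j_high
    i <- pick(j_low)
    res <- list(cutoff = cuts[i], sensitivity = 1 - sens_high[i],
                specificity = 1 - spec_high[i], youden_j = j_low[i],
                direction = "low_positive")
  }
  structure(res, class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Cutoff %.4g (%s): sensitivity %.3f, specificity %.3f, Youden J %.3f\n",
              x$cutoff, x$direction, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}
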