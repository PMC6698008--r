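test_that("identical groups give a null log-rank test and HR near 1", {
  t0 <- c(2, 4, 6, 8, 10, 12); e0 <- c(1, 0, 1, 1, 0, 1)
  fit <- km_logrank(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 6))
  expect_equal(fit$logrank_chisq, 0, tolerance = 1e-8)
  expect_equal(fit$logrank_p, 1, tolerance = 1e-6)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  expect_error(km_logrank(t0, e0, rep("a", 6)), "two")
})

test_that("log-rank statistic matches a hand-computed risk-set oracle", {
  time <- c(1, 3, 4, 5, 8, 9)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- c("a", "b", "a", "b", "a", "b")
  fit <- km_logrank(time, event, group)
  ref <- logrank_oracle(time, event, group)
  expect_equal(fit$logrank_chisq, ref$chisq, tolerance = 1e-8)
  expect_equal(fit$logrank_p, ref$p, tolerance = 1e-8)
})

test_that("asymptotic log-rank p agrees with its permutation distribution", {
  set.seed(202)
  n <- 60
  time <- rexp(n); event <- rbinom(n, 1, 0.7); group <- rep(c("a", "b"), n / 2)
  fit <- km_logrank(time, event, group)
  perm <- replicate(2000, logrank_oracle(time, event, sample(group))$chisq)
  p_perm <- mean(perm >= fit$logrank_chisq)
  expect_lt(abs(p_perm - fit$logrank_p),
            3 * sqrt(max(p_perm, 0.01) * (1 - min(p_perm, 0.99)) / 2000) + 0.02)
})

test_that("KM curves are valid step functions with correct risk sets", {
  set.seed(9)
  time <- rexp(40, 0.1); event <- rbinom(40, 1, 0.6)
  group <- rep(c("lo", "hi"), 20)
  km <- km_logrank(time, event, group)$km_curves
  for (g in unique(km$group)) {
    s <- km$surv[km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("single-event Cox partial likelihood matches a closed-form maximizer", {
  # one event among three subjects; the event subject has the middle
  # covariate value so the maximizer is finite and unique
  time <- c(5, 8, 9); event <- c(1, 0, 0); x <- c(0.5, 0, 1)
  fit <- cox_fit(time, event, data.frame(x = x))
  nll <- function(b) -(b * 0.5 - log(sum(exp(b * x))))
  ref <- optimize(nll, c(-10, 10))$minimum
  expect_equal(fit$coefficients$beta[1], ref, tolerance = 1e-4)
})

test_that("Cox errors are explicit for degenerate inputs", {
  expect_error(cox_fit(1:5, rep(0, 5), data.frame(x = rnorm(5))), "event")
  expect_error(cox_fit(1:5, c(1, 1, 0, 0, 1), data.frame(x = rep(2, 5))),
               "constant")
  # perfect separation: the only events are in one covariate extreme
  time <- c(1, 2, 10, 11, 12, 13)
  event <- c(1, 1, 0, 0, 0, 0)
  x <- c(1, 1, 0, 0, 0, 0)
  expect_error(cox_fit(time, event, data.frame(x = x)),
               "monotone likelihood|non-convergence")
})

test_that("Breslow and Efron tie handling are both available and differ on ties", {
  set.seed(33)
  time <- rep(1:5, each = 4); event <- rbinom(20, 1, 0.7)
  x <- rnorm(20)
  b <- cox_fit(time, event, data.frame(x = x), ties = "breslow")
  e <- cox_fit(time, event, data.frame(x = x), ties = "efron")
  expect_false(isTRUE(all.equal(b$coefficients$beta, e$coefficients$beta)))
})

test_that("backward stepwise retains a strong effect and drops pure noise", {
  spec <- cohort_spec(n_stage2 = 500, n_stage3 = 500,
                      covariate_prevalences = c(angioinvasion = 0.5,
                                                ulceration = 0.5),
                      true_log_hrs = c(angioinvasion = log(2.5)),
                      censor_rate = 0.3, seed = 71)
  gen <- generate_cohort(spec)
  noise <- data.frame(angioinvasion = gen$cohort$angioinvasion,
                      ulceration = gen$cohort$ulceration)
  res <- cox_backward_stepwise(gen$cohort$dfs_months, gen$cohort$dfs_event,
                               noise, p_out = 0.1, horizon_months = 60)
  expect_true("angioinvasion" %in% res$retained$covariate)
  expect_true(all(res$retained$wald_p <= 0.1))
  # removal trace and retained set partition the candidates
  expect_setequal(c(res$retained$covariate, res$removal_trace$covariate),
                  names(noise))
})

test_that("stepwise truncates follow-up at the horizon before fitting", {
  set.seed(3)
  time <- c(10, 20, 70, 80, 90, 100, 30, 55)
  event <- c(1, 1, 1, 1, 1, 1, 0, 1)
  x <- data.frame(x = rnorm(8))
  res <- cox_backward_stepwise(time, event, x, p_out = 1,
                               horizon_months = 60)
  expect_equal(res$final_fit$n_events, sum(event == 1 & time <= 60))
})

test_that("an all-noise candidate set may legitimately end empty", {
  set.seed(13)
  n <- 300
  time <- rexp(n); event <- rbinom(n, 1, 0.7)
  noise <- data.frame(a = rnorm(n), b = rnorm(n))
  res <- cox_backward_stepwise(time, event, noise, p_out = 0.01,
                               horizon_months = Inf)
  expect_true(nrow(res$retained) == 0 || all(res$retained$wald_p <= 0.01))
})

test_that("baseline table: identical groups give p = 1 on count variables", {
  half <- generate_cohort(cohort_spec(n_stage2 = 40, n_stage3 = 0,
                                      seed = 2))$cohort
  dup <- rbind(half, half)
  dup$grp <- rep(c("x", "y"), each = nrow(half))
  tab <- baseline_table(dup, "grp",
                        variables = c("sex", "ulceration", "age"))
  expect_equal(tab$p[tab$variable == "sex" & !is.na(tab$p)], 1)
  expect_equal(tab$p[tab$variable == "ulceration" & !is.na(tab$p)], 1)
})

test_that("baseline table percentages reflect generator prevalences", {
  gen <- generate_cohort(cohort_spec(n_stage2 = 400, n_stage3 = 400,
                                     seed = 44))
  tab <- baseline_table(gen$cohort, "stage",
                        variables = c("ulceration", "angioinvasion"))
  ulc1 <- tab[tab$variable == "ulceration" & tab$level == "1", ]
  pct <- as.numeric(sub(".*\\((.*)\\)", "\\1", ulc1[["stage=II"]]))
  expect_lt(abs(pct / 100 - 0.80), 3 * sqrt(0.8 * 0.2 / 400))
})
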