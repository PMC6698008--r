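#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival curves per group, a two-sided log-rank test, and
#' the between-group hazard ratio with 95% confidence interval from a
#' univariate Cox model (Breslow tie handling). The hazard ratio is for the
#' second factor level versus the first.
#'
#' @param time follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group two-level grouping factor (or coercible).
#' @return an object of class `survival_fit` with `hr`, `ci_low`,
#'   `ci_high`, `logrank_chisq`, `logrank_p`, `wald_p`, `n`, `n_events`,
#'   `groups`, and `km_curves` (data frame `group`, `time`, `surv`,
#'   `n_risk`, `n_event`).
#' @export
km_logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- event[ok]; group <- droplevels(group[ok])
  if (nlevels(group) != 2) stop("group must have exactly two non-empty levels")
  if (any(table(group) == 0)) stop("one group is empty")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- sd_$chisq
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  cx <- cox_fit(time, event,
                data.frame(group = as.integer(group == levels(group)[2])))
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(sf$strata), sf$strata)
  km <- data.frame(group = sub("^group=", "", strata),
                   time = sf$time, surv = sf$surv,
                   n_risk = sf$n.risk, n_event = sf$n.event)
  structure(list(hr = cx$coefficients$hr[1],
                 ci_low = cx$coefficients$ci_low[1],
                 ci_high = cx$coefficients$ci_high[1],
                 logrank_chisq = chisq, logrank_p = p,
                 wald_p = cx$coefficients$wald_p[1],
                 n = length(time), n_events = sum(event),
                 groups = levels(group), km_curves = km),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("%s vs %s: HR %.2f (95%% CI %.2f-%.2f), log-rank p = %.4g (n = %d, events = %d)\n",
              x$groups[2], x$groups[1], x$hr, x$ci_low, x$ci_high,
              x$logrank_p, x$n, x$n_events))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Cox regression (Breslow tie handling by default,
#' Efron available). Hazard ratios are `exp(beta)` with 95% confidence
#' intervals `exp(beta +/- 1.96 se)` and Wald p-values. Non-convergence
#' and monotone likelihood (runaway coefficients from perfect separation)
#' raise explicit errors.
#'
#' @param time follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param covariates data frame or matrix of covariates (numeric; rows with
#'   missing values are dropped listwise).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return an object of class `cox_fit`: `coefficients` (data frame with
#'   `term`, `beta`, `se`, `hr`, `ci_low`, `ci_high`, `wald_p`), `n`,
#'   `n_events`, and the underlying `model`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (sum(df$.event) < 1) stop("need at least one event")
  for (nm in names(covariates))
    if (length(unique(df[[nm]])) < 2)
      stop(sprintf("covariate '%s' is constant across subjects", nm))
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  warned <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("infinite|did not converge|out of iterations", warned)) ||
      any(abs(coef(fit)) > 15))
    stop("Cox fit failed: monotone likelihood or non-convergence (",
         paste(unique(warned), collapse = "; "), ")")
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  coefs <- data.frame(term = names(beta), beta = unname(beta),
                      se = unname(se), hr = exp(unname(beta)),
                      ci_low = exp(unname(beta) - 1.96 * se),
                      ci_high = exp(unname(beta) + 1.96 * se),
                      wald_p = 2 * pnorm(-abs(unname(beta) / se)),
                      row.names = NULL)
  structure(list(coefficients = coefs, n = nrow(df),
                 n_events = sum(df$.event), ties = ties, model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (%s ties), n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Backward-stepwise Cox regression for 5-year disease-free survival
#'
#' Administratively censors follow-up at `horizon_months`, then removes,
#' one at a time, the candidate covariate with the largest Wald p-value
#' exceeding `p_out`, refitting after each removal, until every retained
#' covariate has `p <= p_out` (or the model is empty, a valid result).
#' Removed covariates do not re-enter. If the full model fails to fit, a
#' drop-one retry over the candidates is attempted before giving up.
#'
#' @inheritParams cox_fit
#' @param candidates data frame of candidate covariates.
#' @param p_out stay threshold on the Wald p-value (default 0.1).
#' @param horizon_months administrative censoring horizon (default 60;
#'   `Inf` disables truncation).
#' @return an object of class `stepwise_cox`: `retained` (data frame
#'   `covariate`, `hr`, `ci_low`, `ci_high`, `wald_p`), `removal_trace`
#'   (data frame `covariate`, `p_at_removal`), and `final_fit` (a
#'   [cox_fit()] or `NULL` for the empty model).
#' @export
cox_backward_stepwise <- function(time, event, candidates, p_out = 0.1,
                                  horizon_months = 60,
                                  ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  candidates <- as.data.frame(candidates)
  if (!ncol(candidates)) stop("candidate set is empty")
  if (is.finite(horizon_months)) {
    event <- ifelse(time > horizon_months, 0L, event)
    time <- pmin(time, horizon_months)
  }
  active <- names(candidates)
  trace <- data.frame(covariate = character(0), p_at_removal = numeric(0))

  fit_active <- function(vars) cox_fit(time, event,
                                       candidates[, vars, drop = FALSE],
                                       ties = ties)
  fit <- tryCatch(fit_active(active), error = function(e) e)
  if (inherits(fit, "error") && length(active) > 1) {
    # drop-one retry: remove the first covariate whose absence lets the fit run
    for (v in active) {
      f2 <- tryCatch(fit_active(setdiff(active, v)), error = function(e) e)
      if (!inherits(f2, "error")) {
        trace <- rbind(trace, data.frame(covariate = v, p_at_removal = NA_real_))
        active <- setdiff(active, v); fit <- f2
        break
      }
    }
  }
  if (inherits(fit, "error")) stop("full model failed: ", conditionMessage(fit))

  repeat {
    p <- fit$coefficients$wald_p
    worst <- which.max(p)
    if (p[worst] <= p_out) break
    trace <- rbind(trace, data.frame(covariate = active[worst],
                                     p_at_removal = p[worst]))
    active <- active[-worst]
    if (!length(active)) { fit <- NULL; break }
    fit <- fit_active(active)
  }
  retained <- if (is.null(fit)) {
    data.frame(covariate = character(0), hr = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), wald_p = numeric(0))
  } else {
    with(fit$coefficients,
         data.frame(covariate = term, hr = hr, ci_low = ci_low,
                    ci_high = ci_high, wald_p = wald_p))
  }
  structure(list(retained = retained, removal_trace = trace,
                 final_fit = fit, p_out = p_out,
                 horizon_months = horizon_months),
            class = "stepwise_cox")
}

#' @export
print.stepwise_cox <- function(x, ...) {
  cat(sprintf("Backward-stepwise Cox (p-out = %.2g, horizon = %s months)\n",
              x$p_out, format(x$horizon_months)))
  if (nrow(x$retained)) print(x$retained, digits = 3) else cat("  empty model\n")
  if (nrow(x$removal_trace)) {
    cat("Removed:\n"); print(x$removal_trace, digits = 3)
  }
  invisible(x)
}

#' Baseline characteristics comparison table
#'
#' Compares clinicopathological variables between the two levels of a
#' grouping variable: categorical variables as counts (percent) with an
#' uncorrected Pearson chi-square p-value, continuous variables as
#' mean (sd) with a pooled-variance t-test p-value.
#'
#' @param cohort cohort data frame (see [generate_cohort()]).
#' @param group_by name of a binary grouping column.
#' @param variables columns to compare; defaults to all columns except the
#'   identifiers, the grouping variable and the survival columns.
#' @return data frame with one row per variable level: `variable`, `level`,
#'   one summary column per group, and `p` (on the variable's first row).
#' @export
baseline_table <- function(cohort, group_by, variables = NULL) {
  stopifnot(group_by %in% names(cohort))
  g <- cohort[[group_by]]
  ok <- !is.na(g)
  cohort <- cohort[ok, , drop = FALSE]
  g <- factor(g[ok])
  if (nlevels(g) != 2) stop("grouping variable must have exactly two levels")
  if (is.null(variables))
    variables <- setdiff(names(cohort),
                         c("patient_id", group_by, "dfs_months", "dfs_event"))
  rows <- list()
  for (v in variables) {
    x <- cohort[[v]]
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 6) {
      p <- tryCatch(ttest_ind(x[g == levels(g)[1]], x[g == levels(g)[2]])$p,
                    error = function(e) NA_real_)
      s <- vapply(levels(g), function(l)
        sprintf("%.1f (%.1f)", mean(x[g == l], na.rm = TRUE),
                sd(x[g == l], na.rm = TRUE)), "")
      rows[[length(rows) + 1L]] <-
        data.frame(variable = v, level = "mean (sd)",
                   g1 = s[1], g2 = s[2], p = p)
    } else {
      x <- factor(x)
      tab <- table(x, g)
      p <- tryCatch(pearson_chi2(tab)$p, error = function(e) NA_real_)
      for (i in seq_len(nrow(tab))) {
        s <- vapply(1:2, function(j)
          sprintf("%d (%.1f)", tab[i, j], 100 * tab[i, j] / sum(tab[, j])), "")
        rows[[length(rows) + 1L]] <-
          data.frame(variable = v, level = rownames(tab)[i],
                     g1 = s[1], g2 = s[2],
                     p = if (i == 1) p else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0(group_by, "=", levels(g))
  rownames(out) <- NULL
  out
}
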