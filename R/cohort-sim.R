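#' Synthetic cohort specification
#'
#' Describes a two-stage colon-cancer-like cohort with binary
#' clinicopathological covariates at given prevalences, stage-specific
#' continuous marker distributions (MVD as percent positive tissue area,
#' TSP as percent stroma), ordinal TMA scores, and disease-free survival
#' generated under a proportional-hazards model with an exponential
#' baseline.
#'
#' Event times are drawn as `T ~ Exp(h0 * exp(sum(beta * x)))`. Random
#' censoring uses an independent per-subject exponential whose rate is
#' `censor_rate / (1 - censor_rate)` times the subject's event hazard, so
#' the probability that censoring precedes the event is exactly
#' `censor_rate` for every subject; an administrative cutoff at
#' `admin_censor_months` is applied on top.
#'
#' `true_log_hrs` may name any binary covariate in
#' `covariate_prevalences`, or the derived indicators `mvd_high` /
#' `tsp_high` (marker above its stage-specific distribution median).
#'
#' The defaults emulate the study conditions: 53 stage II and 54 stage III
#' patients, median MVD 5.6% (stage II) and 11.1% (stage III), stroma
#' centred in the mid-40s percent, and roughly a third of follow-up ending
#' in censoring.
#'
#' @param n_stage2,n_stage3 patients per stage.
#' @param covariate_prevalences named vector of binary covariate
#'   prevalences in `[0, 1]`.
#' @param mvd_distribution per-stage lognormal parameters for MVD percent.
#' @param tsp_distribution per-stage normal parameters for TSP percent
#'   (truncated to `[1, 99]`).
#' @param true_log_hrs named vector of true log hazard ratios.
#' @param baseline_hazard exponential baseline hazard per month.
#' @param admin_censor_months administrative censoring horizon.
#' @param censor_rate target probability of random censoring before the
#'   event, in `[0, 1)`.
#' @param missing_marker_rate fraction of patients with all TMA cores
#'   missing (score `NA`).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_stage2 = 53, n_stage3 = 54,
                        covariate_prevalences = c(sex = 0.58,
                                                  right_sided = 0.40,
                                                  ulceration = 0.80,
                                                  angioinvasion = 0.25,
                                                  mucinous = 0.16),
                        mvd_distribution = list(
                          stage2 = list(meanlog = log(5.6), sdlog = 0.55),
                          stage3 = list(meanlog = log(11.1), sdlog = 0.50)),
                        tsp_distribution = list(
                          stage2 = list(mean = 43, sd = 13),
                          stage3 = list(mean = 49, sd = 13)),
                        true_log_hrs = c(),
                        baseline_hazard = 0.012,
                        admin_censor_months = 120,
                        censor_rate = 0.3,
                        missing_marker_rate = 0.04,
                        seed = 1) {
  stopifnot(n_stage2 >= 0, n_stage3 >= 0, baseline_hazard > 0,
            admin_censor_months > 0, censor_rate >= 0, censor_rate < 1,
            missing_marker_rate >= 0, missing_marker_rate < 1)
  if (any(covariate_prevalences < 0 | covariate_prevalences > 1))
    stop("covariate prevalences must lie in [0, 1]")
  # the cohort schema always carries the five named covariates; fill any the
  # caller left out with the defaults
  defaults <- c(sex = 0.58, right_sided = 0.40, ulceration = 0.80,
                angioinvasion = 0.25, mucinous = 0.16)
  miss <- setdiff(names(defaults), names(covariate_prevalences))
  covariate_prevalences <- c(covariate_prevalences, defaults[miss])
  allowed <- c(names(covariate_prevalences), "mvd_high", "tsp_high")
  if (length(true_log_hrs) && !all(names(true_log_hrs) %in% allowed))
    stop("true_log_hrs names must be covariates or mvd_high/tsp_high")
  structure(list(n_stage2 = as.integer(n_stage2),
                 n_stage3 = as.integer(n_stage3),
                 covariate_prevalences = covariate_prevalences,
                 mvd_distribution = mvd_distribution,
                 tsp_distribution = tsp_distribution,
                 true_log_hrs = true_log_hrs,
                 baseline_hazard = baseline_hazard,
                 admin_censor_months = admin_censor_months,
                 censor_rate = censor_rate,
                 missing_marker_rate = missing_marker_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

cohort_schema <- c("patient_id", "stage", "age", "sex", "right_sided",
                   "diameter_mm", "grade", "ulceration", "angioinvasion",
                   "mucinous", "mvd_percent", "tsp_percent", "hif1a_score",
                   "vegfa_score", "dfs_months", "dfs_event")

# six-core ordinal TMA scores for one patient around a latent intensity
sim_tma_score <- function(n, missing_rate) {
  vapply(seq_len(n), function(i) {
    if (runif(1) < missing_rate) return(NA_real_)
    latent <- runif(1, 0, 3)
    cores <- pmin(3, pmax(0, round(latent + rnorm(6, 0, 0.6))))
    cores[runif(6) < 0.08] <- NA # occasional damaged core
    aggregate_tma_scores(cores)
  }, numeric(1))
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort from a [cohort_spec()]: covariates at the stated
#' prevalences, stage-specific marker values, and disease-free survival
#' under the spec's proportional-hazards structure. Deterministic given the
#' spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `cohort` (data frame, one row per patient, columns
#'   `patient_id, stage, age, sex, right_sided, diameter_mm, grade,
#'   ulceration, angioinvasion, mucinous, mvd_percent, tsp_percent,
#'   hif1a_score, vegfa_score, dfs_months, dfs_event`) and `truth`
#'   (`cohort_log_hrs`, `censor_rate`, and the latent `mvd_high` /
#'   `tsp_high` indicators).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_stage2 + spec$n_stage3
  if (n == 0) {
    empty <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cohort_schema)),
                                    cohort_schema))
    empty$patient_id <- character(0); empty$stage <- character(0)
    empty$grade <- character(0)
    return(list(cohort = empty,
                truth = list(cohort_log_hrs = spec$true_log_hrs,
                             censor_rate = spec$censor_rate,
                             mvd_high = integer(0), tsp_high = integer(0))))
  }
  stage <- c(rep("II", spec$n_stage2), rep("III", spec$n_stage3))
  is3 <- stage == "III"

  covs <- sapply(spec$covariate_prevalences,
                 function(p) rbinom(n, 1, p), simplify = FALSE)
  age <- ifelse(is3, rnorm(n, 65.5, 10), rnorm(n, 72.7, 12))
  diameter <- pmax(5, ifelse(is3, rnorm(n, 35, 12), rnorm(n, 40, 20)))
  grade <- sample(c("good", "average", "poor"), n, replace = TRUE,
                  prob = c(0.09, 0.86, 0.05))

  m2 <- spec$mvd_distribution$stage2; m3 <- spec$mvd_distribution$stage3
  mvd <- ifelse(is3, rlnorm(n, m3$meanlog, m3$sdlog),
                rlnorm(n, m2$meanlog, m2$sdlog))
  mvd <- pmin(mvd, 95)
  t2 <- spec$tsp_distribution$stage2; t3 <- spec$tsp_distribution$stage3
  tsp <- ifelse(is3, rnorm(n, t3$mean, t3$sd), rnorm(n, t2$mean, t2$sd))
  tsp <- pmin(pmax(tsp, 1), 99)

  mvd_high <- as.integer(mvd > ifelse(is3, exp(m3$meanlog), exp(m2$meanlog)))
  tsp_high <- as.integer(tsp > ifelse(is3, t3$mean, t2$mean))

  hif1a <- sim_tma_score(n, spec$missing_marker_rate)
  vegfa <- sim_tma_score(n, spec$missing_marker_rate)

  lp <- rep(0, n)
  design <- c(covs, list(mvd_high = mvd_high, tsp_high = tsp_high))
  for (nm in names(spec$true_log_hrs))
    lp <- lp + spec$true_log_hrs[[nm]] * design[[nm]]
  hazard <- spec$baseline_hazard * exp(lp)
  t_event <- rexp(n, rate = hazard)
  if (spec$censor_rate > 0) {
    c_rate <- hazard * spec$censor_rate / (1 - spec$censor_rate)
    t_cens <- rexp(n, rate = c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  dfs_months <- pmin(t_event, t_cens, spec$admin_censor_months)
  dfs_event <- as.integer(t_event <= pmin(t_cens, spec$admin_censor_months))

  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                       stage = stage,
                       age = round(age, 1),
                       sex = covs$sex,
                       right_sided = covs$right_sided,
                       diameter_mm = round(diameter, 1),
                       grade = grade,
                       ulceration = covs$ulceration,
                       angioinvasion = covs$angioinvasion,
                       mucinous = covs$mucinous,
                       mvd_percent = round(mvd, 3),
                       tsp_percent = round(tsp, 3),
                       hif1a_score = round(hif1a, 3),
                       vegfa_score = round(vegfa, 3),
                       dfs_months = dfs_months,
                       dfs_event = dfs_event,
                       stringsAsFactors = FALSE)
  list(cohort = cohort,
       truth = list(cohort_log_hrs = spec$true_log_hrs,
                    censor_rate = spec$censor_rate,
                    mvd_high = mvd_high, tsp_high = tsp_high))
}
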