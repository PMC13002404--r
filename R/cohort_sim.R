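# Subject-level cohort simulator: responder / non-responder groups with
# group-specific ALPS distributions and clinical covariates matching the
# marginal summaries of the study population, plus a logistic-outcome
# generator for regression-recovery testing.

#' Cohort simulation parameters
#'
#' Defaults reproduce the marginal structure of the study cohort: 33
#' responders vs 122 non-responders; ALPS Normal(1.4022, 0.1936) vs
#' Normal(1.3218, 0.1761), truncated at 0; age at onset lognormal matched to
#' medians 24 vs 18 years and their interquartile ranges; prior
#' antiseizure-medication (ASM) burden 2 + Poisson matched to medians 2 vs 3;
#' EEG epileptiform-discharge rates 57.6% vs 78.5%; plus age, sex, MRI
#' abnormality, prior sodium-channel-blocker use and follow-up duration.
#'
#' @param n_responder,n_nonresponder Group sizes.
#' @param alps_mean,alps_sd Length-2 (responder, non-responder) ALPS moments.
#' @param eeg_rate Length-2 EEG epileptiform-discharge probabilities.
#' @param age_onset_meanlog,age_onset_sdlog Length-2 lognormal parameters for
#'   age at seizure onset (years).
#' @param asm_lambda Length-2 Poisson rates; burden = 2 + Poisson(lambda).
#' @param age_mean,age_sd Length-2 age moments (years).
#' @param male_rate,mri_rate,na_blocker_rate Length-2 Bernoulli rates.
#' @param followup_meanlog,followup_sdlog Length-2 lognormal parameters for
#'   follow-up (months).
#' @return A list of class \code{cohort_params}.
#' @export
cohort_params <- function(n_responder = 33L, n_nonresponder = 122L,
                          alps_mean = c(1.4022, 1.3218),
                          alps_sd = c(0.1936, 0.1761),
                          eeg_rate = c(0.576, 0.785),
                          age_onset_meanlog = log(c(24, 18)),
                          age_onset_sdlog = c(log(42 / 14), log(25 / 10)) /
                            (2 * stats::qnorm(0.75)),
                          asm_lambda = c(0.5, 1.2),
                          age_mean = c(41.4, 36.8), age_sd = c(15.7, 13.1),
                          male_rate = c(0.394, 0.459),
                          mri_rate = c(0.636, 0.678),
                          na_blocker_rate = c(0.697, 0.844),
                          followup_meanlog = log(c(64, 65)),
                          followup_sdlog = c(log(76 / 30), log(79 / 33)) /
                            (2 * stats::qnorm(0.75))) {
  p <- list(n_responder = as.integer(n_responder),
            n_nonresponder = as.integer(n_nonresponder),
            alps_mean = alps_mean, alps_sd = alps_sd, eeg_rate = eeg_rate,
            age_onset_meanlog = age_onset_meanlog,
            age_onset_sdlog = age_onset_sdlog, asm_lambda = asm_lambda,
            age_mean = age_mean, age_sd = age_sd, male_rate = male_rate,
            mri_rate = mri_rate, na_blocker_rate = na_blocker_rate,
            followup_meanlog = followup_meanlog, followup_sdlog = followup_sdlog)
  if (p$n_responder <= 0L || p$n_nonresponder <= 0L)
    stop("group sizes must be positive", call. = FALSE)
  if (any(p$alps_sd <= 0)) stop("alps_sd must be positive", call. = FALSE)
  rates <- c(p$eeg_rate, p$male_rate, p$mri_rate, p$na_blocker_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  class(p) <- "cohort_params"
  p
}

rtruncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a responder / non-responder cohort
#'
#' Covariates are drawn independently within group per
#' \code{\link{cohort_params}}; output is deterministic given \code{seed}.
#'
#' @param params A \code{\link{cohort_params}}.
#' @param seed Integer seed.
#' @return A \code{cohort_table} data.frame with one row per subject.
#' @export
simulate_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(seed)
  n <- c(params$n_responder, params$n_nonresponder)
  grp <- rep(c("responder", "non_responder"), n)
  gi <- rep(1:2, n)
  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(sum(n))),
    group = grp,
    alps = rtruncnorm_pos(sum(n), params$alps_mean[gi], params$alps_sd[gi]),
    age = rtruncnorm_pos(sum(n), params$age_mean[gi], params$age_sd[gi]),
    male = stats::runif(sum(n)) < params$male_rate[gi],
    age_onset = stats::rlnorm(sum(n), params$age_onset_meanlog[gi],
                              params$age_onset_sdlog[gi]),
    asm_burden = 2 + stats::rpois(sum(n), params$asm_lambda[gi]),
    eeg_discharges = stats::runif(sum(n)) < params$eeg_rate[gi],
    mri_abnormality = stats::runif(sum(n)) < params$mri_rate[gi],
    na_blocker_prior = stats::runif(sum(n)) < params$na_blocker_rate[gi],
    followup_months = stats::rlnorm(sum(n), params$followup_meanlog[gi],
                                    params$followup_sdlog[gi]),
    stringsAsFactors = FALSE)
  # onset cannot postdate current age (age is bumped, keeping the
  # age-at-onset marginal intact)
  df$age <- pmax(df$age, df$age_onset)
  validate_cohort_table(df)
}

#' Logistic outcome scenario
#'
#' Describes a data-generating process outcome ~ Bernoulli(plogis(X beta))
#' over independently drawn covariates, used to verify that the regression
#' machinery recovers known coefficients.
#'
#' @param coefficients Named numeric vector; must include
#'   \code{"(Intercept)"}; remaining names must match covariate specs.
#' @param covariates Named list of specs, each
#'   \code{list(type = "normal", mean =, sd =)} or
#'   \code{list(type = "bernoulli", rate =)}.
#' @param n Number of subjects.
#' @return A list of class \code{logistic_scenario}.
#' @export
logistic_scenario <- function(coefficients, covariates = list(), n = 155L) {
  if (!"(Intercept)" %in% names(coefficients))
    stop("coefficients must include '(Intercept)'", call. = FALSE)
  if (any(!is.finite(coefficients)))
    stop("coefficients must be finite", call. = FALSE)
  vars <- setdiff(names(coefficients), "(Intercept)")
  if (!setequal(vars, names(covariates)))
    stop("covariate specs must match coefficient names", call. = FALSE)
  structure(list(coefficients = coefficients, covariates = covariates,
                 n = as.integer(n)),
            class = "logistic_scenario")
}

draw_covariate <- function(spec, n) {
  switch(spec$type,
         normal = stats::rnorm(n, spec$mean, spec$sd),
         bernoulli = as.numeric(stats::runif(n) < spec$rate),
         stop(sprintf("unknown covariate type '%s'", spec$type), call. = FALSE))
}

#' Simulate binary outcomes from a logistic model
#'
#' @param scenario A \code{\link{logistic_scenario}}.
#' @param seed Integer seed.
#' @return data.frame with the covariates and binary \code{outcome} (0/1).
#' @export
simulate_logistic_outcomes <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "logistic_scenario"))
  set.seed(seed)
  n <- scenario$n
  vars <- setdiff(names(scenario$coefficients), "(Intercept)")
  X <- vapply(vars, function(v) draw_covariate(scenario$covariates[[v]], n),
              numeric(n))
  if (length(vars) == 0L) X <- matrix(0, n, 0)
  eta <- scenario$coefficients[["(Intercept)"]] +
    if (length(vars)) drop(X %*% scenario$coefficients[vars]) else 0
  out <- as.integer(stats::runif(n) < stats::plogis(eta))
  df <- as.data.frame(X)
  df$outcome <- out
  df
}
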