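# End-to-end orchestration: phantom simulation -> ALPS recovery, cohort
# simulation -> the full statistical plan, with seed-derived stage RNG and
# machine-readable outputs.

#' Derive a stage-specific seed from a master seed
#'
#' Stable hash of (seed, stage label), kept inside the 32-bit integer range
#' so each pipeline stage is independently reproducible.
#'
#' @param seed Master integer seed.
#' @param stage Stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

comparison_record <- function(res) {
  list(method = res$method, statistic = res$statistic,
       df = res$degrees_of_freedom, p = res$p_two_tailed)
}

#' Run the full statistical plan on a cohort table
#'
#' Reproduces the study's analysis surface on any responder / non-responder
#' cohort: per-covariate two-group comparisons (test chosen by variable type
#' and, for continuous variables, a normality gate), the pooled t-test on
#' the ALPS index, ROC analysis of ALPS for predicting response with the
#' Youden-optimal cutoff, a univariate screen at \code{alpha} feeding a
#' multivariable logistic regression for non-response with backward
#' elimination, and post-hoc power of the ALPS comparison.
#'
#' @param cohort A cohort data.frame (see \code{\link{read_cohort_table}}).
#' @param alpha Significance level used throughout.
#' @param removal_alpha Backward-elimination retention threshold.
#' @return A list of class \code{cohort_analysis} with elements
#'   \code{group_counts}, \code{comparisons}, \code{alps_ttest}, \code{roc},
#'   \code{screen}, \code{logistic} (final fit with \code{full_fit} and
#'   \code{trace}) and \code{power}.
#' @export
analyze_cohort <- function(cohort, alpha = 0.05, removal_alpha = 0.05) {
  cohort <- validate_cohort_table(as.data.frame(cohort))
  resp <- cohort$group == "responder"
  if (!any(resp) || all(resp))
    stop("cohort must contain both responders and non-responders", call. = FALSE)
  covars <- intersect(c("age", "male", "age_onset", "followup_months",
                        "asm_burden", "na_blocker_prior", "mri_abnormality",
                        "eeg_discharges", "alps"), names(cohort))
  screen <- univariate_screen(cohort, "group", covars, alpha = alpha)
  comparisons <- stats::setNames(lapply(covars, function(v) {
    row <- screen[screen$variable == v, ]
    list(variable = v, test = row$test, p = row$p)
  }), covars)
  alps_t <- ttest_raw(cohort$alps[resp], cohort$alps[!resp], "pooled")
  roc <- roc_analysis(cohort$alps, cohort$group, positive_label = "responder",
                      direction = "higher")
  selected <- setdiff(attr(screen, "selected"), character(0))
  logistic <- NULL
  if (length(selected)) {
    X <- cohort[selected]
    for (cn in names(X)) if (is.logical(X[[cn]])) X[[cn]] <- as.numeric(X[[cn]])
    y <- as.integer(!resp)            # model the odds of NON-response
    logistic <- backward_eliminate(X, y, removal_alpha = removal_alpha)
  }
  power <- posthoc_power_ttest(mean(cohort$alps[resp]), stats::sd(cohort$alps[resp]),
                               sum(resp), mean(cohort$alps[!resp]),
                               stats::sd(cohort$alps[!resp]), sum(!resp),
                               alpha = alpha)
  structure(list(group_counts = c(responder = sum(resp),
                                  non_responder = sum(!resp)),
                 comparisons = comparisons, alps_ttest = alps_t, roc = roc,
                 screen = screen, logistic = logistic, power = power,
                 alpha = alpha),
            class = "cohort_analysis")
}

logistic_record <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(terms = names(fit$coefficients),
       coefficients = unname(fit$coefficients), se = unname(fit$se),
       odds_ratio = unname(fit$odds_ratio),
       ci_lower = unname(fit$ci_lower), ci_upper = unname(fit$ci_upper),
       p_wald = unname(fit$p_wald), converged = fit$converged,
       separation = fit$separation)
}

#' Serialize a cohort analysis to plain lists (JSON-ready)
#'
#' @param analysis A \code{\link{analyze_cohort}} result.
#' @return A nested list of plain vectors.
#' @export
analysis_report <- function(analysis) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  lg <- analysis$logistic
  list(group_counts = as.list(analysis$group_counts),
       univariate = lapply(analysis$comparisons, function(c)
         list(test = c$test, p = c$p)),
       alps_ttest = comparison_record(analysis$alps_ttest),
       roc = list(auc = analysis$roc$auc, auc_se = analysis$roc$auc_se,
                  p_vs_half = analysis$roc$p_vs_half,
                  optimal_cutoff = analysis$roc$optimal_cutoff,
                  sensitivity = analysis$roc$sensitivity,
                  specificity = analysis$roc$specificity),
       logistic_full = logistic_record(if (!is.null(lg)) lg$full_fit),
       logistic_final = logistic_record(lg),
       elimination_trace = if (!is.null(lg)) lg$trace,
       posthoc_power = analysis$power)
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Cohort: %d responders, %d non-responders\n",
              x$group_counts["responder"], x$group_counts["non_responder"]))
  cat(sprintf("ALPS pooled t-test: t = %.3f, p = %.4g\n",
              x$alps_ttest$statistic, x$alps_ttest$p_two_tailed))
  cat(sprintf("ROC: AUC = %.3f (p vs 0.5 = %.4g), cutoff %.4f\n",
              x$roc$auc, x$roc$p_vs_half, x$roc$optimal_cutoff))
  if (!is.null(x$logistic))
    cat(sprintf("Logistic (backward elimination): retained %s\n",
                paste(x$logistic$retained, collapse = ", ")))
  cat(sprintf("Post-hoc power of the ALPS comparison: %.3f\n", x$power))
  invisible(x)
}

#' Write a human-readable cohort analysis report
#'
#' @param analysis A \code{\link{analyze_cohort}} result.
#' @param path Destination text file.
#' @return The path, invisibly.
#' @export
write_text_report <- function(analysis, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Cohort analysis report")
  w("======================")
  w("Responders: %d, non-responders: %d",
    analysis$group_counts["responder"], analysis$group_counts["non_responder"])
  w("")
  w("Univariate comparisons (test, two-tailed p):")
  for (v in names(analysis$comparisons)) {
    c <- analysis$comparisons[[v]]
    w("  %-18s %-45s p = %.4g", v, c$test, c$p)
  }
  w("")
  w("ALPS pooled t-test: t = %.4f (df = %g), p = %.4g",
    analysis$alps_ttest$statistic, analysis$alps_ttest$degrees_of_freedom,
    analysis$alps_ttest$p_two_tailed)
  w("Post-hoc power at alpha = %.2f: %.4f", analysis$alpha, analysis$power)
  w("")
  w("ROC of ALPS for response: AUC = %.4f (SE %.4f), p vs 0.5 = %.4g",
    analysis$roc$auc, analysis$roc$auc_se, analysis$roc$p_vs_half)
  w("  optimal cutoff %.4f: sensitivity %.3f, specificity %.3f",
    analysis$roc$optimal_cutoff, analysis$roc$sensitivity,
    analysis$roc$specificity)
  if (!is.null(analysis$logistic)) {
    w("")
    w("Multivariable logistic regression (outcome: non-response)")
    fmt_fit <- function(fit, label) {
      w("  %s:", label)
      for (i in seq_along(fit$coefficients))
        w("    %-18s coef %8.4f  OR %7.3f (95%% CI %.3f-%.3f)  p = %.4g",
          names(fit$coefficients)[i], fit$coefficients[i], fit$odds_ratio[i],
          fit$ci_lower[i], fit$ci_upper[i], fit$p_wald[i])
    }
    fmt_fit(analysis$logistic$full_fit, "full model")
    fmt_fit(analysis$logistic, "after backward elimination")
    tr <- analysis$logistic$trace
    if (nrow(tr) > 1)
      for (i in 2:nrow(tr))
        w("  step %d: removed %s (p = %.4g)", tr$step[i], tr$removed[i],
          tr$p_removed[i])
  }
  invisible(path)
}

#' Run the complete simulation study
#'
#' Stages: (1) simulate a DWI phantom, write it to disk, read it back and
#' recover the ALPS index through the full mask / tensor-fit / selection
#' pipeline; (2) simulate a responder / non-responder cohort; (3) run the
#' statistical plan on the cohort. All randomness derives from \code{seed}
#' via per-stage hashed seeds; outputs are byte-identical across reruns.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param layout Phantom layout (default: standard layout at SNR 30).
#' @param scheme Gradient scheme.
#' @param params Cohort parameters.
#' @param alpha,removal_alpha Significance and elimination thresholds.
#' @return Invisibly, a list with \code{alps} (pipeline result),
#'   \code{truth_alps}, \code{cohort}, \code{analysis} and \code{files}.
#' @export
run_full_study <- function(out_dir, seed = 1L,
                           layout = phantom_layout(snr = 30),
                           scheme = default_gradient_scheme(),
                           params = cohort_params(),
                           alpha = 0.05, removal_alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # stage 1: phantom -> files -> ALPS recovery
  sim <- simulate_dwi(layout, scheme, seed = derive_seed(seed, "phantom"))
  files <- write_phantom(sim, out_dir, "phantom")
  dwi <- read_volume(files[["nii"]])
  sch <- read_gradient_scheme(files[["bval"]], files[["bvec"]])
  alps <- alps_pipeline(dwi, sch, default_roi_spec(layout))
  truth <- truth_alps(layout)
  jsonlite::write_json(
    list(seed = seed,
         alps = alps$alps, per_hemisphere = as.list(alps$per_hemisphere),
         mode = alps$mode, true_alps = truth$bilateral_mean,
         relative_error = abs(alps$alps - truth$bilateral_mean) /
           truth$bilateral_mean),
    file.path(out_dir, "alps_result.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  # stage 2: cohort
  cohort <- simulate_cohort(params, seed = derive_seed(seed, "cohort"))
  write_cohort_table(cohort, file.path(out_dir, "cohort.csv"))
  # stage 3: statistics
  analysis <- analyze_cohort(cohort, alpha = alpha,
                             removal_alpha = removal_alpha)
  jsonlite::write_json(analysis_report(analysis),
                       file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  utils::write.csv(analysis$roc$curve, file.path(out_dir, "roc_curve.csv"),
                   row.names = FALSE)
  write_text_report(analysis, file.path(out_dir, "report.txt"))
  invisible(list(alps = alps, truth_alps = truth, cohort = cohort,
                 analysis = analysis,
                 files = c(files,
                           alps_json = file.path(out_dir, "alps_result.json"),
                           cohort_csv = file.path(out_dir, "cohort.csv"),
                           analysis_json = file.path(out_dir, "analysis.json"),
                           roc_csv = file.path(out_dir, "roc_curve.csv"),
                           report = file.path(out_dir, "report.txt"))))
}
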