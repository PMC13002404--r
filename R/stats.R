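# Cohort statistics: two-group comparisons (from raw data or published
# summary statistics), Mann-Whitney U with exact small-sample inference,
# 2x2 chi-square, ROC with DeLong variance and Youden cutoff, logistic
# regression with univariate screening and backward elimination, and
# post-hoc power for the pooled two-sample t-test.

group_comparison <- function(method, statistic, df, p, groups) {
  structure(list(method = method, statistic = unname(statistic),
                 degrees_of_freedom = if (is.null(df)) NULL else unname(df),
                 p_two_tailed = min(1, max(0, unname(p))), groups = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g\n", x$method, x$statistic,
              if (!is.null(x$degrees_of_freedom))
                sprintf(" (df = %.4g)", x$degrees_of_freedom) else "",
              x$p_two_tailed))
  invisible(x)
}

#' Two-sample t-test from summary statistics
#'
#' Computes the independent-samples t-test directly from published group
#' means, SDs and sizes — the form needed to check printed p-values when raw
#' data are unavailable. The pooled (Student) variant uses
#' sp^2 = ((n1-1)s1^2 + (n2-1)s2^2)/(n1+n2-2) with df = n1+n2-2; the Welch
#' variant uses the Satterthwaite df.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param variant "pooled" (default) or "welch".
#' @return A \code{group_comparison} with statistic, df and two-tailed p.
#' @export
ttest_summary <- function(m1, s1, n1, m2, s2, n2,
                          variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0) stop("SDs must be nonnegative", call. = FALSE)
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
    if (m1 == m2) df <- n1 + n2 - 2
  } else {
    t <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  group_comparison(paste0(variant, " t-test (summary)"), t, df, p,
                   list(list(n = n1, mean = m1, sd = s1),
                        list(n = n2, mean = m2, sd = s2)))
}

#' Two-sample t-test on raw samples
#'
#' Delegates to \code{\link{ttest_summary}} applied to the samples' own
#' summaries, so the two entry points can never disagree. Zero variance in
#' both groups with equal means yields p = 1 by convention.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param variant "pooled" or "welch".
#' @return A \code{group_comparison}.
#' @export
ttest_raw <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2", call. = FALSE)
  ttest_summary(mean(x), stats::sd(x), length(x),
                mean(y), stats::sd(y), length(y), variant)
}

mw_u_stat <- function(x, y) {
  r <- rank(c(x, y))                     # midranks
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' U is computed from midranks. When the product n1*n2 <= 400 and the data
#' are tie-free, the exact null distribution is used; with ties, full
#' enumeration of group labelings is used when combinatorially feasible;
#' otherwise a normal approximation with tie and continuity corrections.
#' Two-sided p is 2 * min(P(U <= u), P(U >= u)), capped at 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Largest n1*n2 for which exact inference is attempted.
#' @return A \code{group_comparison}; \code{statistic} is U for sample x,
#'   with the method label recording which inference path was used.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 400) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty", call. = FALSE)
  u <- mw_u_stat(x, y)
  ties <- anyDuplicated(c(x, y)) > 0L
  method <- "Mann-Whitney U"
  if (n1 * n2 <= exact_limit && !ties) {
    p_le <- stats::pwilcox(u, n1, n2)
    p_ge <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- paste(method, "(exact)")
  } else if (n1 * n2 <= exact_limit && choose(n1 + n2, n1) <= 2e5) {
    r <- rank(c(x, y))
    us <- utils::combn(n1 + n2, n1, function(ix) sum(r[ix])) -
      n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(us <= u + eps), mean(us >= u - eps)))
    method <- paste(method, "(exact, enumerated with ties)")
  } else {
    N <- n1 + n2
    r <- rank(c(x, y))
    tie_sizes <- table(r)
    tie_corr <- sum(tie_sizes^3 - tie_sizes) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_corr)
    mu <- n1 * n2 / 2
    if (v <= 0) {
      p <- 1
      z <- 0
    } else {
      cc <- sign(u - mu) * 0.5          # continuity correction toward the mean
      z <- (u - mu - cc) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- paste(method, "(normal approximation)")
  }
  group_comparison(method, u, NULL, p,
                   list(list(n = n1, median = stats::median(x),
                             iqr = unname(stats::quantile(x, c(0.25, 0.75)))),
                        list(n = n2, median = stats::median(y),
                             iqr = unname(stats::quantile(y, c(0.25, 0.75))))))
}

#' Chi-square test of a 2x2 table
#'
#' Pearson chi-square with df = 1; the Yates continuity correction is off by
#' default. A zero margin is an error (an exact test would be needed there).
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @param yates Apply the continuity correction?
#' @return A \code{group_comparison}.
#' @export
chi_square_2x2 <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("counts must be a 2x2 matrix", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin: chi-square undefined, use an exact test", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  group_comparison(sprintf("chi-square (2x2%s)", if (yates) ", Yates" else ""),
                   ct$statistic, ct$parameter, ct$p.value,
                   list(counts = counts))
}

#' ROC analysis with DeLong variance and Youden-optimal cutoff
#'
#' Builds the empirical ROC over all distinct score thresholds, computes the
#' trapezoidal AUC (identical to the tie-corrected Mann-Whitney U / (n1 n2)),
#' its DeLong standard error (O(n log n) midrank form), a normal-theory
#' p-value against AUC = 0.5, and the cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1 (ties resolved toward higher
#' sensitivity). A subject is called positive when its score is >= the
#' cutoff (\code{direction = "higher"}) or <= it (\code{"lower"}).
#'
#' @param scores Numeric predictor values.
#' @param labels Class labels, same length.
#' @param positive_label The label treated as positive.
#' @param direction "higher" (default): larger scores indicate the positive
#'   class; "lower": smaller scores do.
#' @return A list of class \code{roc_result}: \code{auc}, \code{auc_se},
#'   \code{p_vs_half}, \code{optimal_cutoff}, \code{sensitivity},
#'   \code{specificity}, \code{youden}, and \code{curve} (data.frame of
#'   threshold, fpr, tpr from (0,0) to (1,1)).
#' @export
roc_analysis <- function(scores, labels, positive_label,
                         direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive_label
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  s <- if (direction == "higher") scores else -scores
  x <- s[pos]; y <- s[!pos]
  # empirical curve over distinct thresholds, descending (sort + cumsum)
  ord <- order(s, decreasing = TRUE)
  ss <- s[ord]; pp <- pos[ord]
  last <- which(ss != c(ss[-1], NA) | seq_along(ss) == length(ss))
  thr <- ss[last]
  tpr <- cumsum(pp)[last] / n1
  fpr <- cumsum(!pp)[last] / n0
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1)
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  # DeLong components via midranks (placement values)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0          # P(Y < x_i) + 0.5 P(=)
  v01 <- (r_all[n1 + seq_len(n0)] - rank(y)) / n1
  v01 <- 1 - v01                                       # orient toward positives
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  p_half <- if (is.na(se) || se == 0) {
    if (abs(auc - 0.5) < .Machine$double.eps^0.5) 1 else 0
  } else 2 * stats::pnorm(-abs(auc - 0.5) / se)
  # Youden-optimal cutoff over observed thresholds
  j <- tpr + (1 - fpr) - 1
  best <- which(j == max(j))
  best <- best[which.max(tpr[best])]                   # ties -> higher sensitivity
  cutoff <- thr[best]
  if (direction == "lower") cutoff <- -cutoff
  structure(list(auc = auc, auc_se = se, p_vs_half = min(1, p_half),
                 optimal_cutoff = cutoff, sensitivity = tpr[best],
                 specificity = 1 - fpr[best], youden = j[best],
                 direction = direction, n_positive = n1, n_negative = n0,
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (SE %.3f, p vs 0.5 = %.4g)\n",
              x$auc, x$auc_se, x$p_vs_half))
  cat(sprintf("optimal cutoff = %.4f (sens %.3f, spec %.3f, Youden %.3f)\n",
              x$optimal_cutoff, x$sensitivity, x$specificity, x$youden))
  invisible(x)
}

#' Multivariable logistic regression
#'
#' Binomial maximum likelihood by iteratively reweighted least squares (via
#' \code{stats::glm}), reporting Wald standard errors, odds ratios with 95%
#' normal-theory confidence intervals, and convergence / separation flags.
#' Quasi-separation never fails silently: the fit is returned flagged.
#'
#' @param X data.frame or matrix of covariates (intercept added internally).
#' @param y Binary response (0/1, logical, or two-level factor).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return An object of class \code{logistic_fit}: \code{coefficients},
#'   \code{se}, \code{odds_ratio}, \code{ci_lower}, \code{ci_upper},
#'   \code{p_wald}, \code{converged}, \code{separation}, \code{n_iter},
#'   and the underlying \code{glm} object.
#' @export
logistic_regression <- function(X, y, max_iter = 50L, tol = 1e-8) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary", call. = FALSE)
  if (is.null(X) || (is.data.frame(X) && ncol(X) == 0) ||
      (is.matrix(X) && ncol(X) == 0)) {
    df <- data.frame(y = y)
    fml <- y ~ 1
  } else {
    df <- as.data.frame(X)
    for (cn in names(df)) if (is.logical(df[[cn]])) df[[cn]] <- as.numeric(df[[cn]])
    zero_var <- vapply(df, function(v) stats::var(as.numeric(v)) == 0, logical(1))
    if (any(zero_var))
      stop(sprintf("constant covariate(s): %s",
                   paste(names(df)[zero_var], collapse = ", ")), call. = FALSE)
    df$y <- y
    fml <- stats::as.formula(paste("y ~", paste(setdiff(names(df), "y"),
                                                collapse = " + ")))
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(maxit = max_iter, epsilon = tol)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  cf <- stats::setNames(co[, "Estimate"], rownames(co))
  se <- stats::setNames(co[, "Std. Error"], rownames(co))
  res <- structure(list(
    coefficients = cf,
    se = se,
    odds_ratio = exp(cf),
    ci_lower = exp(cf - 1.96 * se),
    ci_upper = exp(cf + 1.96 * se),
    p_wald = stats::setNames(co[, "Pr(>|z|)"], rownames(co)),
    converged = fit$converged && !separation,
    separation = separation,
    n_iter = fit$iter,
    n = length(y),
    glm = fit), class = "logistic_fit")
  if (!res$converged)
    warning("logistic fit flagged: ", if (separation)
      "quasi-complete separation detected" else "IRLS did not converge",
      call. = FALSE)
  res
}

#' @export
print.logistic_fit <- function(x, ...) {
  tab <- data.frame(coefficient = x$coefficients, odds_ratio = x$odds_ratio,
                    ci_low = x$ci_lower, ci_high = x$ci_upper, p = x$p_wald)
  print(round(tab, 4))
  if (!x$converged) cat("NOTE: fit flagged (separation or non-convergence)\n")
  invisible(x)
}

#' D'Agostino-Pearson K-squared normality test
#'
#' Omnibus test combining the transformed sample skewness and kurtosis;
#' K^2 ~ chi-square(2) under normality. Requires n >= 8.
#'
#' @param x Numeric sample.
#' @return List with \code{statistic} (K^2), \code{p}, and the component
#'   z-scores \code{z_skew} and \code{z_kurt}.
#' @export
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 8) stop("K-squared test requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("zero variance: normality test undefined", call. = FALSE)
  b1 <- m3 / m2^1.5
  # skewness (D'Agostino 1970)
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z_skew <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1_b2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1_b2 * (2 / sqb1_b2 + sqrt(1 + 4 / sqb1_b2^2))
  z_kurt <- ((1 - 2 / (9 * A)) -
             ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p = stats::pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt)
}

#' Univariate screen of candidate predictors
#'
#' Applies, per variable, the two-group test matching its type: chi-square
#' for binary variables, and for continuous ones either the pooled t-test or
#' the Mann-Whitney U test. In \code{"auto"} mode the continuous test is
#' chosen by the D'Agostino-Pearson normality test at alpha = 0.05 in each
#' group (Mann-Whitney when either group is non-normal or too small for the
#' test). Variables with p below \code{alpha} are selected.
#'
#' @param cohort A cohort data.frame.
#' @param outcome Name of the two-level grouping column.
#' @param candidate_vars Character vector of column names to screen.
#' @param alpha Selection threshold for the two-sided p-value.
#' @param continuous_test "auto" (default), "ttest" or "mannwhitney".
#' @return data.frame with columns variable, test, p, selected; the selected
#'   names are in \code{attr(, "selected")}.
#' @export
univariate_screen <- function(cohort, outcome, candidate_vars, alpha = 0.05,
                              continuous_test = c("auto", "ttest", "mannwhitney")) {
  continuous_test <- match.arg(continuous_test)
  gvals <- unique(cohort[[outcome]])
  if (length(gvals) != 2L)
    stop("outcome must have exactly two levels", call. = FALSE)
  g1 <- cohort[[outcome]] == gvals[1]
  rows <- lapply(candidate_vars, function(v) {
    x <- cohort[[v]][g1]; y <- cohort[[v]][!g1]
    if (is.logical(cohort[[v]]) ||
        all(cohort[[v]] %in% c(0, 1, TRUE, FALSE))) {
      tab <- rbind(c(sum(x %in% c(1, TRUE)), sum(!(x %in% c(1, TRUE)))),
                   c(sum(y %in% c(1, TRUE)), sum(!(y %in% c(1, TRUE)))))
      res <- tryCatch(chi_square_2x2(tab),
                      error = function(e) NULL)
      if (is.null(res)) return(data.frame(variable = v, test = "chi-square",
                                          p = NA_real_))
    } else {
      use_t <- switch(continuous_test,
                      ttest = TRUE, mannwhitney = FALSE,
                      auto = length(x) >= 8 && length(y) >= 8 &&
                        stats::var(x) > 0 && stats::var(y) > 0 &&
                        dagostino_k2(x)$p >= 0.05 && dagostino_k2(y)$p >= 0.05)
      res <- if (use_t) ttest_raw(x, y) else mann_whitney_u(x, y)
    }
    data.frame(variable = v, test = res$method, p = res$p_two_tailed)
  })
  out <- do.call(rbind, rows)
  out$selected <- !is.na(out$p) & out$p < alpha
  attr(out, "selected") <- out$variable[out$selected]
  out
}

#' Backward elimination for logistic regression
#'
#' Starting from the full model, repeatedly removes the non-intercept term
#' with the largest Wald p-value while that p-value is at or above
#' \code{removal_alpha}, refitting after each removal. Both the full
#' (pre-elimination) model and the elimination trace are retained.
#'
#' @param X data.frame of candidate covariates.
#' @param y Binary response.
#' @param removal_alpha Retention threshold (a term stays when p < alpha).
#' @return The final \code{logistic_fit}, with attributes-like extra fields:
#'   \code{full_fit} (the initial model) and \code{trace} (data.frame of
#'   step, removed variable, its p-value, and remaining term count).
#' @export
backward_eliminate <- function(X, y, removal_alpha = 0.05) {
  X <- as.data.frame(X)
  fit <- logistic_regression(X, y)
  full_fit <- fit
  trace <- data.frame(step = 0L, removed = NA_character_, p_removed = NA_real_,
                      n_terms = ncol(X), stringsAsFactors = FALSE)
  vars <- names(X)
  step <- 0L
  repeat {
    pv <- fit$p_wald[setdiff(names(fit$p_wald), "(Intercept)")]
    if (!length(pv) || max(pv) < removal_alpha) break
    worst <- names(pv)[which.max(pv)]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = worst,
                                     p_removed = unname(max(pv)),
                                     n_terms = length(vars) - 1L,
                                     stringsAsFactors = FALSE))
    vars <- setdiff(vars, worst)
    fit <- logistic_regression(X[vars], y)
  }
  fit$full_fit <- full_fit
  fit$trace <- trace
  fit$retained <- vars
  fit
}

#' Post-hoc power of the pooled two-sample t-test
#'
#' Two-sided power at level \code{alpha} from the noncentral t distribution,
#' with noncentrality d * sqrt(n1 n2 / (n1 + n2)) where d = (m1 - m2) / sp
#' is the pooled-SD standardized effect observed in the data.
#'
#' @param m1,s1,n1,m2,s2,n2 Group summaries as in \code{\link{ttest_summary}}.
#' @param alpha Two-sided significance level.
#' @return The power (a number in [alpha, 1]).
#' @export
posthoc_power_ttest <- function(m1, s1, n1, m2, s2, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  d <- (m1 - m2) / sp
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
}
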