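test_that("summary-statistic t-test reproduces printed and analytic values", {
  # study ALPS row: pooled p prints as 0.024
  r <- ttest_summary(1.4022, 0.1936, 33, 1.3218, 0.1761, 122, "pooled")
  expect_equal(round(r$p_two_tailed, 3), 0.024)
  expect_equal(r$degrees_of_freedom, 153)
  # equal means: t = 0, p = 1
  r0 <- ttest_summary(5, 1, 10, 5, 2, 12)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_two_tailed, 1)
  # Welch variant on the same summaries
  rw <- ttest_summary(1.4022, 0.1936, 33, 1.3218, 0.1761, 122, "welch")
  expect_equal(round(rw$p_two_tailed, 3), 0.036)
})

test_that("raw t-test agrees with base t.test and with its own summaries", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    mine <- ttest_raw(x, y, "pooled")
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_two_tailed, ref$p.value, tolerance = 1e-12)
    mw <- ttest_raw(x, y, "welch")
    refw <- t.test(x, y)
    expect_equal(mw$p_two_tailed, refw$p.value, tolerance = 1e-12)
    # consistency with the summary entry point
    ms <- ttest_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    expect_equal(mine$statistic, ms$statistic, tolerance = 1e-14)
  }
  # degenerate: identical constant samples -> p = 1 convention
  expect_equal(ttest_raw(rep(3, 5), rep(3, 7))$p_two_tailed, 1)
  expect_equal(ttest_raw(c(1, 1, 1), c(1, 1, 1))$statistic, 0)
})

test_that("Mann-Whitney U matches enumeration, wilcox.test and its extremes", {
  # complete separation: U = n1 * n2
  mw <- mann_whitney_u(6:10, 1:5)
  expect_equal(mw$statistic, 25)
  # identical samples: p ~ 1
  expect_gte(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_two_tailed, 0.99)
  set.seed(9)
  # tie-free exact path equals wilcox.test's exact p
  for (i in 1:15) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    mine <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_two_tailed, ref$p.value, tolerance = 1e-12)
    # and equals brute-force enumeration over all labelings
    expect_equal(mine$p_two_tailed, mw_enum_p(x, y), tolerance = 1e-12)
  }
  # tied data: enumerated exact equals the brute-force oracle
  for (i in 1:10) {
    x <- sample(1:4, 6, replace = TRUE); y <- sample(1:4, 5, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_two_tailed, mw_enum_p(x, y),
                 tolerance = 1e-12)
  }
  # the continuity-corrected normal approximation tracks the exact p within
  # its enumerated worst-case deviation at these sizes (0.0173 at n1=n2=5,
  # shrinking to 0.0109 at n1=n2=8)
  for (i in 1:20) {
    n1 <- sample(5:8, 1); n2 <- sample(5:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    exact <- mann_whitney_u(x, y)$p_two_tailed
    approx <- mann_whitney_u(x, y, exact_limit = 0)$p_two_tailed
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("2x2 chi-square matches the closed form and base chisq.test", {
  # balanced table: no association
  r0 <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_two_tailed, 1)
  # closed-form oracle: N (ad - bc)^2 / product of margins
  tab <- matrix(c(19, 96, 14, 26), 2)   # EEG-discharge style counts
  a <- 19; b <- 14; c <- 96; d <- 26; N <- a + b + c + d
  chi_oracle <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  r <- chi_square_2x2(tab)
  expect_equal(r$statistic, chi_oracle, tolerance = 1e-12)
  expect_equal(round(r$statistic, 3), 6.047)
  expect_equal(round(r$p_two_tailed, 3), 0.014)
  # Yates variant agrees with chisq.test(correct = TRUE)
  ry <- chi_square_2x2(tab, yates = TRUE)
  ref <- chisq.test(tab, correct = TRUE)
  expect_equal(ry$statistic, unname(ref$statistic), tolerance = 1e-12)
  # doubling all cells doubles the statistic
  expect_equal(chi_square_2x2(2 * tab)$statistic, 2 * r$statistic,
               tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 6), 2)), "margin")
})

test_that("ROC analysis matches pROC and the Mann-Whitney identity", {
  # perfect separation
  r <- roc_analysis(c(1, 2, 3, 11, 12, 13), rep(c("n", "p"), each = 3), "p")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$optimal_cutoff > 3 && r$optimal_cutoff <= 11)
  # constant scores: AUC = 0.5
  expect_equal(roc_analysis(rep(1, 10), rep(c("n", "p"), 5), "p")$auc, 0.5)
  set.seed(13)
  for (i in 1:10) {
    n1 <- sample(10:40, 1); n0 <- sample(10:40, 1)
    sc <- c(round(rnorm(n1, 0.5), 1), round(rnorm(n0), 1))   # rounding -> ties
    lb <- rep(c("p", "n"), c(n1, n0))
    mine <- roc_analysis(sc, lb, "p")
    # AUC equals tie-corrected U / (n1 n2)
    r_all <- rank(sc)
    u <- sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2
    expect_equal(mine$auc, u / (n1 * n0), tolerance = 1e-12)
    # pROC cross-check: AUC and DeLong variance
    ref <- pROC::roc(lb, sc, levels = c("n", "p"), direction = "<",
                     quiet = TRUE)
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(mine$auc_se^2, pROC::var(ref), tolerance = 1e-10)
    # curve is monotone from (0,0) to (1,1) and integrates to the AUC
    expect_true(all(diff(mine$curve$fpr) >= 0))
    expect_true(all(diff(mine$curve$tpr) >= 0))
    expect_equal(mine$curve$fpr[1], 0); expect_equal(mine$curve$tpr[1], 0)
    expect_equal(tail(mine$curve$fpr, 1), 1)
    expect_equal(tail(mine$curve$tpr, 1), 1)
    # Youden cutoff is the empirical maximizer
    sens <- vapply(mine$curve$threshold, function(t) mean(sc[lb == "p"] >= t),
                   numeric(1))
    spec <- vapply(mine$curve$threshold, function(t) mean(sc[lb == "n"] < t),
                   numeric(1))
    expect_equal(mine$youden, max(sens + spec - 1), tolerance = 1e-12)
  }
  # direction = "lower": flipping scores is equivalent
  sc <- rnorm(60); lb <- rep(c("p", "n"), 30)
  lo <- roc_analysis(sc, lb, "p", direction = "lower")
  hi <- roc_analysis(-sc, lb, "p", direction = "higher")
  expect_equal(lo$auc, hi$auc, tolerance = 1e-12)
  expect_equal(lo$optimal_cutoff, -hi$optimal_cutoff, tolerance = 1e-12)
  expect_error(roc_analysis(1:5, rep("p", 5), "p"), "both classes")
})

test_that("logistic regression reproduces closed-form fits and flags separation", {
  # intercept-only MLE is the log odds of the observed rate
  f <- logistic_regression(NULL, c(rep(1, 122), rep(0, 33)))
  expect_equal(unname(f$coefficients["(Intercept)"]), log(122 / 33),
               tolerance = 1e-8)
  # single binary covariate: slope = ln(ad/bc) of the 2x2 table
  x <- rep(c(0, 1), c(60, 40))
  y <- c(rep(c(1, 0), c(20, 40)), rep(c(1, 0), c(25, 15)))
  f2 <- logistic_regression(data.frame(x = x), y)
  or_closed <- (25 / 15) / (20 / 40)
  expect_equal(unname(f2$coefficients["x"]), log(or_closed), tolerance = 1e-8)
  expect_equal(unname(f2$odds_ratio["x"]), or_closed, tolerance = 1e-6)
  expect_equal(unname(f2$ci_lower["x"]),
               exp(f2$coefficients["x"] - 1.96 * f2$se["x"]),
               ignore_attr = TRUE, tolerance = 1e-12)
  # perfectly separated data are flagged, not silently returned
  xs <- c(rnorm(20, -3), rnorm(20, 3)); ys <- rep(c(0, 1), each = 20)
  expect_warning(fs <- logistic_regression(data.frame(x = xs), ys), "separation")
  expect_false(fs$converged)
  expect_true(fs$separation)
  expect_error(logistic_regression(data.frame(z = rep(1, 10)),
                                   rep(c(0, 1), 5)), "constant")
})

test_that("D'Agostino-Pearson K2 matches an independent reference implementation", {
  x <- c(1.370958, -0.564698, 0.363128, 0.632863, 0.404268, -0.106125,
         1.511522, -0.094659, 2.018424, -0.062714, 1.30487, 2.286645,
         -1.388861, -0.278789, -0.133321, 0.63595, -0.284253, -2.656455,
         -2.440467, 1.320113, -0.306639, -1.781308, -0.171917, 1.214675,
         1.895193, -0.430469, -0.257269, -1.763163, 0.460097, -0.639995)
  r <- dagostino_k2(x)
  expect_equal(r$statistic, 0.6151798666, tolerance = 1e-8)
  expect_equal(r$p, 0.7352167441, tolerance = 1e-8)
  y <- c(0.048346, 1.622008, 1.713138, 0.812194, 0.545624, 2.620266,
         0.751857, 4.273072, 0.204633, 0.045502, 0.94422, 0.748027,
         1.872008, 1.86744, 1.210334, 0.34524, 0.676928, 0.95789, 0.519402,
         0.914632, 2.400547, 0.632578, 0.397221, 0.440159, 0.548117,
         0.255522, 0.445979, 1.240472, 1.688621, 1.884121, 1.258145,
         0.788752, 1.921636, 0.008784, 0.527681, 0.387338, 0.088108,
         0.318174, 0.926782, 0.892091)
  r2 <- dagostino_k2(y)
  expect_equal(r2$statistic, 24.21207268, tolerance = 1e-8)
  expect_equal(r2$p, 5.5261e-06, tolerance = 1e-4)
  expect_error(dagostino_k2(rnorm(5)), "n >= 8")
})

test_that("univariate screening selects by p-value and variable type", {
  set.seed(17)
  co <- simulate_cohort(cohort_params(n_responder = 3000,
                                      n_nonresponder = 3000), seed = 17)
  scr <- univariate_screen(co, "group",
                           c("alps", "age_onset", "asm_burden",
                             "eeg_discharges", "mri_abnormality"))
  sel <- attr(scr, "selected")
  # strong group effects are all detected at this n
  expect_true(all(c("alps", "age_onset", "asm_burden", "eeg_discharges")
                  %in% sel))
  # constant variable is excluded
  co$flat <- 1
  co$flatb <- FALSE
  scr2 <- univariate_screen(co, "group", c("alps", "flat", "flatb"))
  expect_false("flat" %in% attr(scr2, "selected"))
  expect_false("flatb" %in% attr(scr2, "selected"))
  # alpha = 1 selects every testable candidate
  scr3 <- univariate_screen(co, "group", c("alps", "age", "asm_burden"),
                            alpha = 1)
  expect_equal(attr(scr3, "selected"), c("alps", "age", "asm_burden"))
})

test_that("backward elimination removes noise terms and respects its threshold", {
  beta <- c("(Intercept)" = -0.3, signal = 1.5)
  sc <- logistic_scenario(
    beta, covariates = list(signal = list(type = "normal", mean = 0, sd = 1)),
    n = 5000)
  d <- simulate_logistic_outcomes(sc, seed = 19)
  set.seed(101); d$noise <- rnorm(nrow(d))
  fit <- backward_eliminate(d[c("signal", "noise")], d$outcome)
  # the pure-noise covariate is eliminated first; the signal survives
  expect_equal(fit$trace$removed[2], "noise")
  expect_equal(fit$retained, "signal")
  expect_true("noise" %in% names(fit$full_fit$coefficients))
  # all-significant model: zero removals, trace length 1
  fit2 <- backward_eliminate(d["signal"], d$outcome)
  expect_equal(nrow(fit2$trace), 1L)
  expect_equal(fit2$retained, "signal")
  # removal_alpha = 0 makes retention impossible: every term is stripped
  fit3 <- backward_eliminate(d[c("signal", "noise")], d$outcome,
                             removal_alpha = 0)
  expect_equal(fit3$retained, character(0))
  expect_equal(names(fit3$coefficients), "(Intercept)")
  expect_equal(nrow(fit3$trace), 3L)
})

test_that("post-hoc power follows the noncentral t and its limits", {
  # null effect: power equals alpha
  expect_equal(posthoc_power_ttest(5, 1, 30, 5, 1, 30, alpha = 0.05), 0.05,
               tolerance = 1e-10)
  # study summaries: power ~ 0.62, cross-checked by Monte Carlo simulation
  pw <- posthoc_power_ttest(1.4022, 0.1936, 33, 1.3218, 0.1761, 122)
  expect_equal(round(pw, 2), 0.62)
  set.seed(23)
  reps <- 4000
  hits <- mean(replicate(reps, {
    x <- rnorm(33, 1.4022, 0.1936); y <- rnorm(122, 1.3218, 0.1761)
    ttest_raw(x, y)$p_two_tailed < 0.05
  }))
  expect_lt(abs(hits - pw), 4 * sqrt(pw * (1 - pw) / reps))
  # growing n drives power to 1
  expect_gt(posthoc_power_ttest(1.4022, 0.1936, 3300, 1.3218, 0.1761, 12200),
            0.999)
})
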