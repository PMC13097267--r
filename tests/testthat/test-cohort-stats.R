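test_that("the normality gate routes skewed data to Mann-Whitney and clean normals to t", {
  set.seed(51)
  skewed <- list(rexp(50, rate = 1), rexp(50, rate = 1))
  expect_equal(normality_gate(skewed), "mann_whitney")
  # inverse-CDF points of a normal are as normal as a sample can be
  normals <- list(qnorm(ppoints(30), 5, 2), qnorm(ppoints(30), 7, 2))
  expect_equal(normality_gate(normals), "t_test")
  # constant groups cannot be tested and fall back to the nonparametric branch
  expect_equal(normality_gate(list(rep(3, 10), rnorm(10))), "mann_whitney")
  expect_error(normality_gate(list(c(1, 2), rnorm(10))), "at least 3")
})

test_that("compare_feature applies the gated test with matching summaries", {
  # interleaved tie-free groups: U = mn/2, exact two-sided p = 1
  tab <- data.frame(response = rep(c("responsive", "unresponsive"), each = 4),
                    f = c(1, 4, 5, 8, 2, 3, 6, 7))
  res <- compare_feature(tab, "f", test = "mann_whitney")
  expect_equal(res$test_used, "mann_whitney")
  expect_equal(res$p_value, 1)
  expect_true(grepl("\\(", res$group_summaries$responsive$text))  # median (IQR)

  # complete separation: U = 0 for the low group
  tab2 <- data.frame(response = rep(c("responsive", "unresponsive"), each = 3),
                     f = c(1, 2, 3, 101, 102, 103))
  res2 <- compare_feature(tab2, "f", test = "mann_whitney")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, oracle_mw_p(c(1, 2, 3), c(101, 102, 103)))

  # a heavily skewed feature fails the gate and routes to Mann-Whitney
  set.seed(50)
  tab_skew <- data.frame(response = rep(c("responsive", "unresponsive"), each = 30),
                         f = rexp(60))
  expect_equal(compare_feature(tab_skew, "f")$test_used, "mann_whitney")

  # near-normal groups take the t branch and mean +/- SD summaries
  tab3 <- data.frame(response = rep(c("responsive", "unresponsive"), each = 30),
                     f = c(qnorm(ppoints(30), 10, 2), qnorm(ppoints(30), 12, 2)))
  res3 <- compare_feature(tab3, "f")
  expect_equal(res3$test_used, "t_test")
  expect_true(grepl("±", res3$group_summaries$responsive$text))
})

test_that("Mann-Whitney p-values match exhaustive permutation enumeration", {
  set.seed(52)
  for (i in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    v <- sample(1:100, n1 + n2)  # tie-free
    x <- v[1:n1]; y <- v[-(1:n1)]
    tab <- data.frame(response = c(rep("responsive", n1), rep("unresponsive", n2)),
                      f = c(x, y))
    res <- compare_feature(tab, "f", test = "mann_whitney")
    expect_equal(res$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("Pearson chi-square follows the O/E formula and its symmetries", {
  even <- chi_square_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  diag40 <- chi_square_test(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag40$statistic, 40)
  expect_equal(diag40$df, 1)

  set.seed(53)
  tabm <- matrix(rpois(6, 15) + 1, nrow = 2)
  expect_equal(chi_square_test(tabm)$statistic, chi_square_test(tabm[2:1, ])$statistic)
  expect_equal(chi_square_test(tabm)$df, 2)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("ICC(2,1) is exact on a frozen two-rater fixture", {
  # expected values computed independently with a variance-component
  # implementation of two-way random-effects absolute-agreement single-rater ICC
  r1 <- c(3.1, 4.5, 2.2, 5.8, 4.9, 3.3, 6.1, 2.7, 5.2, 4.0)
  r2 <- c(3.4, 4.1, 2.6, 5.5, 5.3, 3.0, 6.4, 2.9, 4.8, 4.3)
  res <- icc_agreement(cbind(r1, r2))
  expect_equal(res$icc, 0.966555953829458, tolerance = 1e-10)
  expect_equal(round(res$ci_low, 2), 0.87)
  expect_equal(round(res$ci_high, 2), 0.99)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
})

test_that("ICC behaves like an agreement measure", {
  set.seed(54)
  subj <- rnorm(50, 10, 3)
  expect_equal(icc_agreement(cbind(subj, subj))$icc, 1)
  # shared shift leaves absolute agreement untouched
  noisy <- cbind(subj, subj + rnorm(50, 0, 1))
  expect_equal(icc_agreement(noisy)$icc, icc_agreement(noisy + 100)$icc, tolerance = 1e-12)
  # overwhelming rater noise destroys agreement
  wrecked <- cbind(subj, subj + rnorm(50, 0, 30))
  expect_lt(icc_agreement(wrecked)$icc, 0.2)
  # agreement decreases monotonically along a noise ladder
  iccs <- vapply(c(0.5, 2, 8, 32), function(s) {
    set.seed(55)
    icc_agreement(cbind(subj, subj + rnorm(50, 0, s)))$icc
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
  expect_error(icc_agreement(cbind(rep(1, 10), rep(1, 10))), "between-subject")
})

test_that("correlation is method-gated and banded at 0.40/0.60/0.80", {
  x <- as.numeric(1:30)
  res <- correlate(x, x^3)  # monotone, heavily non-normal
  expect_equal(res$method, "spearman")
  expect_equal(res$r, 1)
  expect_equal(res$band, "excellent")

  set.seed(56)
  xn <- rnorm(200); yn <- rnorm(200)
  null_res <- correlate(xn, yn)
  expect_lt(abs(null_res$r), 0.2)
  expect_equal(null_res$band, "poor")

  expect_equal(correlation_band(0.35), "poor")
  expect_equal(correlation_band(0.40), "moderate")
  expect_equal(correlation_band(-0.5999999), "moderate")
  expect_equal(correlation_band(0.60), "good")
  expect_equal(correlation_band(0.7999999), "good")
  expect_equal(correlation_band(-0.80), "excellent")
  expect_error(correlate(rep(1, 10), rnorm(10)), "constant")
})

test_that("logistic combination reduces to closed forms on degenerate designs", {
  set.seed(57)
  n <- 40
  y <- rep(c("responsive", "unresponsive"), each = n / 2)
  # uninformative all-zero feature: intercept = logit(prevalence)
  tab <- data.frame(response = y, f0 = rep(0, n), f1 = rnorm(n))
  fit0 <- fit_logistic(tab, "f0")
  expect_equal(unname(fit0$coefficients["(Intercept)", "Estimate"]),
               qlogis(mean(y == "responsive")), tolerance = 1e-8)
  expect_true(all(abs(fit0$fitted - 0.5) < 1e-8))

  # near-separable single feature: fitted probabilities approach the labels
  tab$fsep <- ifelse(y == "responsive", 1, 0) + rnorm(n, 0, 1e-3)
  fits <- fit_logistic(tab, "fsep")
  expect_true(all(abs(fits$fitted - (y == "responsive")) < 0.01))

  # exact separation trips the detection flag
  tab$fperf <- ifelse(y == "responsive", 1, -1)
  fitp <- fit_logistic(tab, "fperf")
  expect_true(fitp$separation)
  expect_false(fitp$converged)

  expect_error(fit_logistic(tab[c(1:8, 21:27), ], c("f0", "f1")), "observations")
})

test_that("in-sample logistic combination dominates its single features", {
  set.seed(58)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  a <- y * 1.2 + rnorm(n)
  b <- y * 1.2 + rnorm(n)  # independent second signal
  tab <- data.frame(response = ifelse(y == 1, "responsive", "unresponsive"), a = a, b = b)
  rep_tab <- evaluate_response_markers(tab, c("a", "b"))
  auc_comb <- rep_tab$auc[rep_tab$parameter == "combined_model"]
  auc_singles <- rep_tab$auc[rep_tab$parameter != "combined_model"]
  expect_gte(auc_comb, max(auc_singles) - 1e-9)
  expect_equal(rep_tab$cutoff_rule[rep_tab$parameter == "combined_model"], "-")
})

test_that("ROC analysis matches brute-force concordance and exhaustive Youden search", {
  # perfectly separated scores
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$cutoff, 2)  # "> 2" separates exactly
  expect_equal(r$direction, "greater_is_positive")

  set.seed(59)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    y <- c(TRUE, FALSE, runif(n - 2) > 0.5)  # both classes guaranteed
    scores <- sample(1:8, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
    r <- roc_analysis(scores, y, positive = TRUE)
    auc_g <- oracle_auc(scores[y], scores[!y])
    expect_equal(r$auc, if (r$direction == "greater_is_positive") auc_g else 1 - auc_g,
                 tolerance = 1e-12)
    expect_gte(r$auc, 0.5)
    oy <- oracle_youden(scores, y, r$direction)
    expect_equal(r$cutoff, oy$cutoff)
    expect_equal(r$sensitivity, 100 * oy$sens)
    expect_equal(r$specificity, 100 * oy$spec)
  }
})

test_that("DeLong AUC confidence intervals agree with pROC", {
  set.seed(60)
  for (i in 1:10) {
    n <- 80
    y <- rep(c(1, 0), each = n / 2)
    scores <- y * runif(1, 0.5, 2) + rnorm(n)
    r <- roc_analysis(scores, y, positive = 1)
    pr <- pROC::roc(y, scores, direction = if (r$direction == "greater_is_positive") "<" else ">",
                    levels = c(0, 1), quiet = TRUE)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$ci_low, max(0, ci[1]), tolerance = 1e-9)
    expect_equal(r$ci_high, min(1, ci[3]), tolerance = 1e-9)
  }
})

test_that("null scores give chance-level AUC, fixed-direction, within sampling bounds", {
  set.seed(61)
  scores <- rnorm(500)
  y <- rep(c(TRUE, FALSE), 250)
  auc_fixed <- roc_analysis(scores, y, direction = "greater_is_positive",
                            positive = TRUE)$auc
  expect_gt(auc_fixed, 0.45); expect_lt(auc_fixed, 0.55)
  expect_gte(roc_analysis(scores, y, positive = TRUE)$auc, 0.5)
  expect_error(roc_analysis(scores, rep(TRUE, 500), positive = TRUE), "both classes")
})
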