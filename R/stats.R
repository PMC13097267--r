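#' Choose the group-comparison test by a normality gate
#'
#' Shapiro-Wilk is applied to each group; the parametric branch (Student's
#' t-test) is taken only when no group rejects normality at `alpha`.
#' Constant-valued groups cannot be tested for normality and route to the
#' nonparametric branch.
#'
#' @param values_by_group List of numeric vectors, one per group, each with
#'   at least 3 non-missing values.
#' @param alpha Gate level (default 0.05).
#' @return `"t_test"` or `"mann_whitney"`.
#' @export
normality_gate <- function(values_by_group, alpha = 0.05) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2)
  for (v in values_by_group) {
    v <- v[!is.na(v)]
    if (length(v) < 3) stop("each group needs at least 3 non-missing values", call. = FALSE)
    if (diff(range(v)) == 0) return("mann_whitney")
    # shapiro.test caps n at 5000; subsample is never needed at cohort scale
    if (stats::shapiro.test(v)$p.value < alpha) return("mann_whitney")
  }
  "t_test"
}

#' Compare one feature between response groups
#'
#' Applies the normality-gated test to a feature column of the cohort table:
#' Student's t-test with mean +/- SD summaries when both groups pass
#' Shapiro-Wilk, otherwise the Mann-Whitney U test with median (IQR)
#' summaries. Missing values (e.g. undefined delta-percent where the pre
#' value was zero) are dropped per group.
#'
#' @param table Feature table from [cohort_feature_table()] (or any
#'   data.frame with the feature column and a group column).
#' @param feature_name Column to compare.
#' @param group_col Grouping column (default `"response"`).
#' @param test `"auto"` (default) applies the normality gate; `"t_test"` or
#'   `"mann_whitney"` force one branch.
#' @return A list of class `group_comparison`: `feature_name`, `test_used`,
#'   `statistic`, `p_value`, and `group_summaries` (named list of per-group
#'   summary strings plus the numbers behind them).
#' @export
compare_feature <- function(table, feature_name, group_col = "response",
                            test = c("auto", "t_test", "mann_whitney")) {
  test <- match.arg(test)
  stopifnot(feature_name %in% names(table), group_col %in% names(table))
  groups <- split(table[[feature_name]], table[[group_col]])
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(vapply(groups, length, 1L) == 0)) {
    stop(sprintf("feature '%s': a group is empty after dropping missing values",
                 feature_name), call. = FALSE)
  }
  if (test == "auto") test <- normality_gate(groups)
  if (test == "t_test") {
    ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    summaries <- lapply(groups, function(v) {
      list(mean = mean(v), sd = stats::sd(v),
           text = sprintf("%.2f ± %.2f", mean(v), stats::sd(v)))
    })
  } else {
    ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
    summaries <- lapply(groups, function(v) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      list(median = q[2], q1 = q[1], q3 = q[3],
           text = sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3]))
    })
  }
  structure(list(feature_name = feature_name, test_used = test,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 group_summaries = summaries),
            class = "group_comparison")
}

#' Pearson's chi-square test on a contingency table
#'
#' Classical (uncorrected) Pearson statistic
#' \eqn{\sum (O - E)^2 / E} with expected counts from the margins and
#' `df = (rows - 1)(cols - 1)`, for categorical covariates such as sex or
#' smoking status.
#'
#' @param contingency Matrix of non-negative counts (typically 2 x K).
#' @return A list of class `group_comparison` with `test_used =
#'   "chi_square"`, the statistic, `df` and `p_value`.
#' @export
chi_square_test <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (any(contingency < 0) || sum(contingency) == 0) {
    stop("contingency table must be non-negative with positive total", call. = FALSE)
  }
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stop("contingency table has a zero margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  structure(list(feature_name = "contingency", test_used = "chi_square",
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "group_comparison")
}

#' Intraclass correlation for measurement agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (ICC(2,1) in the Shrout-Fleiss taxonomy), the standard form for
#' intra-/inter-observer agreement of image measurements, with the F-based
#' 95% confidence interval of McGraw & Wong.
#'
#' @param measurements Numeric matrix, subjects in rows and the two (or
#'   more) ratings in columns; at least 5 subjects.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `model` descriptor.
#' @export
icc_agreement <- function(measurements, conf_level = 0.95) {
  m <- as.matrix(measurements)
  if (any(is.na(m))) stop("missing ratings are not supported", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 5 || k < 2) stop("need at least 5 subjects and 2 ratings", call. = FALSE)
  grand <- mean(m)
  row_means <- rowMeans(m); col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0) stop("zero between-subject variance: ICC undefined", call. = FALSE)
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    ci <- c(1, 1)  # ratings identical: agreement is exact
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(max(-1, min(lo, icc)), min(1, max(hi, icc)))
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 model = "two-way random effects, absolute agreement, single measure"),
            class = "icc_result")
}

#' Correlation with normality-gated method and banded interpretation
#'
#' Pearson when both variables pass Shapiro-Wilk at 0.05, Spearman
#' otherwise. The absolute coefficient is banded as poor (< 0.40), moderate
#' (0.40 to < 0.60), good (0.60 to < 0.80) or excellent (>= 0.80).
#'
#' @param x,y Paired numeric vectors; pairs with a missing member are
#'   dropped; at least 3 complete pairs required.
#' @return A list of class `correlation_result`: `r`, `p_value`, `method`,
#'   `band`, `n`.
#' @export
correlate <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("constant variable: correlation undefined", call. = FALSE)
  }
  normal <- function(v) stats::shapiro.test(v)$p.value >= 0.05
  method <- if (normal(x) && normal(y)) "pearson" else "spearman"
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  structure(list(r = unname(ht$estimate), p_value = ht$p.value, method = method,
                 band = correlation_band(unname(ht$estimate)), n = length(x)),
            class = "correlation_result")
}

#' Band an absolute correlation coefficient
#'
#' @param r Correlation coefficient.
#' @return `"poor"` (|r| < 0.40), `"moderate"` (0.40 to < 0.60), `"good"`
#'   (0.60 to < 0.80) or `"excellent"` (>= 0.80).
#' @export
correlation_band <- function(r) {
  a <- abs(r)
  if (a < 0.40) "poor"
  else if (a < 0.60) "moderate"
  else if (a < 0.80) "good"
  else "excellent"
}

#' Binary logistic combination of features
#'
#' Unpenalized maximum-likelihood logistic regression of the response label
#' on the given features. The fitted probability of the positive class is
#' the combined score used for ROC analysis. Complete (quasi-)separation is
#' detected and flagged; coefficients are then reported as non-converged.
#'
#' @param table Feature table.
#' @param feature_names Character vector of predictor columns; at least 10
#'   observations per feature are required.
#' @param label Column holding the binary label (default `"response"`).
#' @param positive Value of `label` treated as the positive class (default
#'   `"responsive"`).
#' @return A list of class `logistic_model`: `coefficients` (with Wald
#'   p-values), `fitted` probabilities, `linear_predictor`, `converged`,
#'   `separation`, and the row index used after dropping missing values.
#' @export
fit_logistic <- function(table, feature_names, label = "response",
                         positive = "responsive") {
  stopifnot(all(feature_names %in% names(table)), label %in% names(table))
  dat <- table[, c(label, feature_names)]
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  y <- as.integer(dat[[label]] == positive)
  if (length(unique(y)) < 2) stop("label must take both values", call. = FALSE)
  if (nrow(dat) < 10 * length(feature_names)) {
    stop(sprintf("need >= %d observations for %d feature(s), got %d",
                 10 * length(feature_names), length(feature_names), nrow(dat)),
         call. = FALSE)
  }
  form <- stats::as.formula(paste(".y ~", paste(feature_names, collapse = " + ")))
  dat$.y <- y
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned_sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  coefs <- summary(fit)$coefficients
  fitted <- as.numeric(stats::fitted(fit))
  # fitted probabilities indistinguishable from 0/1 mean (quasi-)separation,
  # whether or not glm itself warned
  separated <- warned_sep || any(fitted < 1e-8) || any(fitted > 1 - 1e-8)
  # keep probabilities strictly inside (0,1)
  eps <- 1e-12
  fitted <- pmin(pmax(fitted, eps), 1 - eps)
  structure(list(coefficients = coefs, fitted = fitted,
                 linear_predictor = as.numeric(fit$linear.predictors),
                 converged = fit$converged && !separated,
                 separation = separated,
                 rows_used = which(keep), y = y),
            class = "logistic_model")
}

#' ROC analysis with Youden-optimal cutoff
#'
#' The AUC is the concordance fraction between positive and negative scores
#' with half credit for ties (equivalently the trapezoidal area under the
#' empirical ROC curve). The direction is chosen automatically so that
#' AUC >= 0.5 unless fixed by the caller. The operating cutoff is the
#' observed score maximizing the Youden index (sensitivity + specificity
#' - 1), with ties broken toward higher specificity; for
#' `direction = "greater_is_positive"` the rule is "score > cutoff", for
#' `"lesser_is_positive"` it is "score <= cutoff". The 95% CI of the AUC
#' uses the DeLong variance estimate.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (same length); `positive` marks the positive
#'   class.
#' @param direction `"auto"` (default), `"greater_is_positive"` or
#'   `"lesser_is_positive"`.
#' @param positive Value of `labels` treated as positive (default
#'   `"responsive"` when labels are character, else the larger of the two
#'   values).
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `direction`, `sensitivity` and `specificity` (percent),
#'   `youden`, `p_value` (DeLong test of AUC = 0.5), `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels,
                         direction = c("auto", "greater_is_positive", "lesser_is_positive"),
                         positive = NULL, conf_level = 0.95) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (is.null(positive)) {
    positive <- if (is.character(labels) && "responsive" %in% labels) "responsive"
                else max(labels)
  }
  y <- labels == positive
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  pos <- scores[y]; neg <- scores[!y]
  auc_greater <- concordance_auc(pos, neg)
  if (direction == "auto") {
    direction <- if (auc_greater >= 0.5) "greater_is_positive" else "lesser_is_positive"
  }
  auc <- if (direction == "greater_is_positive") auc_greater else 1 - auc_greater
  # DeLong placements under the chosen direction
  sp <- if (direction == "greater_is_positive") scores else -scores
  vr <- delong_variance(sp[y], sp[!y])
  se <- sqrt(vr)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  p_value <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else 0
  cut <- youden_cutoff(scores, y, direction)
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 cutoff = cut$cutoff, direction = direction,
                 sensitivity = cut$sensitivity, specificity = cut$specificity,
                 youden = cut$youden, p_value = p_value,
                 n_pos = sum(y), n_neg = sum(!y)),
            class = "roc_result")
}

# concordance fraction with half credit for ties, computed from midranks
# (the Mann-Whitney statistic scaled to [0,1])
concordance_auc <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

delong_variance <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  psi <- function(x, yv) (outer(x, yv, ">") + 0.5 * outer(x, yv, "=="))
  mat <- psi(pos, neg)
  v10 <- rowMeans(mat)   # placement of each positive among negatives
  v01 <- 1 - colMeans(mat)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(1 - v01) else 0
  s10 / m + s01 / n
}

youden_cutoff <- function(scores, y, direction) {
  cand <- sort(unique(scores))
  best <- NULL
  for (c0 in cand) {
    pred_pos <- if (direction == "greater_is_positive") scores > c0 else scores <= c0
    sens <- mean(pred_pos[y])
    spec <- mean(!pred_pos[!y])
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 && spec > best$specificity / 100 + 1e-12)) {
      best <- list(cutoff = c0, sensitivity = 100 * sens, specificity = 100 * spec,
                   youden = j)
    }
  }
  best
}

#' Evaluate candidate treatment-response markers
#'
#' Runs the marker evaluation on a cohort feature table: an ROC
#' analysis for each candidate feature alone, and for the unpenalized
#' logistic combination of all of them (scored by fitted probability). The
#' combined model reports no cutoff - its score is a probability whose scale
#' is not a feature unit.
#'
#' @param table Feature table from [cohort_feature_table()].
#' @param feature_names Candidate marker columns; defaults to the absolute
#'   change in myosteatosis (LH) volume and the percent change in
#'   whole-region volume.
#' @param label,positive Binary label column and positive class.
#' @return A `data.frame` of class `marker_report`, one row per marker plus
#'   one for the combined model: `parameter`, `cutoff`, `cutoff_rule`,
#'   `auc`, `ci_low`, `ci_high`, `sensitivity`, `specificity`, `p_value`.
#' @export
evaluate_response_markers <- function(table,
                                      feature_names = c("d_volume_LH", "dpct_volume_whole"),
                                      label = "response", positive = "responsive") {
  stopifnot(all(feature_names %in% names(table)))
  rows <- lapply(feature_names, function(f) {
    keep <- !is.na(table[[f]])
    roc <- roc_analysis(table[[f]][keep], table[[label]][keep], positive = positive)
    data.frame(parameter = f,
               cutoff = roc$cutoff,
               cutoff_rule = if (roc$direction == "greater_is_positive")
                 sprintf("> %.4g", roc$cutoff) else sprintf("<= %.4g", roc$cutoff),
               auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
               sensitivity = roc$sensitivity, specificity = roc$specificity,
               p_value = roc$p_value, stringsAsFactors = FALSE)
  })
  model <- fit_logistic(table, feature_names, label = label, positive = positive)
  roc_c <- roc_analysis(model$fitted, model$y, positive = 1,
                        direction = "greater_is_positive")
  rows <- c(rows, list(data.frame(parameter = "combined_model",
                                  cutoff = NA_real_, cutoff_rule = "-",
                                  auc = roc_c$auc, ci_low = roc_c$ci_low,
                                  ci_high = roc_c$ci_high,
                                  sensitivity = roc_c$sensitivity,
                                  specificity = roc_c$specificity,
                                  p_value = roc_c$p_value,
                                  stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("marker_report", "data.frame")
  attr(out, "model") <- model
  out
}
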