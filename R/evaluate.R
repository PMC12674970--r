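#' Regression error metrics for trough predictions
#'
#' MAE = mean |pred - obs|, RMSE = sqrt(mean (pred - obs)^2), and MAPE on the
#' 0-100 scale = 100 * mean(|pred - obs| / obs). Pairs whose observed trough
#' falls below `mape_min_obs` are excluded from the MAPE (with a warning) to
#' avoid ratio blow-up from near-zero denominators.
#'
#' @param pred,obs Equal-length numeric vectors (mg/L).
#' @param mape_min_obs Minimum observed value admitted into the MAPE.
#' @return A list of class `metrics_report`: `mae`, `rmse`, `mape`, `n`.
#' @export
regression_metrics <- function(pred, obs, mape_min_obs = 0.5) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  if (length(pred) < 1) stop("need at least one pair")
  err <- pred - obs
  ok <- obs >= mape_min_obs
  if (!all(ok)) {
    warning(sprintf("%d pair(s) with observed trough < %.2g mg/L excluded from MAPE",
                    sum(!ok), mape_min_obs))
  }
  structure(list(
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    mape = if (any(ok)) 100 * mean(abs(err[ok]) / obs[ok]) else NA_real_,
    n = length(pred)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Trough prediction error (n = %d)\n", x$n))
  cat(sprintf("  MAE  %6.2f mg/L\n  RMSE %6.2f mg/L\n  MAPE %6.2f %%\n",
              x$mae, x$rmse, x$mape))
  invisible(x)
}

#' Therapeutic category of a trough value
#'
#' Classifies a trough against its patient-specific goal range: below the
#' lower bound is subtherapeutic, above the upper bound supratherapeutic,
#' and the bounds themselves count as therapeutic (inclusive on both ends).
#'
#' @param value Trough value(s), mg/L.
#' @param lower,upper Range bounds, mg/L (`0 < lower < upper`). Vectorized.
#' @return Factor with levels `subtherapeutic`, `therapeutic`,
#'   `supratherapeutic`.
#' @export
classify_trough <- function(value, lower, upper) {
  if (any(lower <= 0) || any(lower >= upper)) stop("invalid therapeutic range")
  out <- ifelse(value < lower, "subtherapeutic",
                ifelse(value > upper, "supratherapeutic", "therapeutic"))
  factor(out, levels = c("subtherapeutic", "therapeutic", "supratherapeutic"))
}

#' Therapeutic-category confusion matrix and accuracy
#'
#' Classifies predicted and measured troughs with each instance's own goal
#' range and tallies the 3x3 confusion matrix (rows: predicted category,
#' columns: measured category). Accuracy is the trace over the total.
#'
#' @param pred,obs Predicted and measured troughs (mg/L), aligned.
#' @param lower,upper Per-instance range bounds.
#' @return A list of class `confusion3`: `matrix` (3x3 counts), `accuracy`,
#'   `n`, and `measured_marginal` (column sums).
#' @export
confusion_accuracy <- function(pred, obs, lower, upper) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  pc <- classify_trough(pred, lower, upper)
  oc <- classify_trough(obs, lower, upper)
  m <- table(predicted = pc, measured = oc)
  structure(list(matrix = unclass(m),
                 accuracy = sum(diag(m)) / sum(m),
                 n = sum(m),
                 measured_marginal = colSums(m)),
            class = "confusion3")
}

#' Bland-Altman agreement between predicted and measured troughs
#'
#' Differences d = pred - obs summarized by their mean (bias), sample
#' standard deviation, and the 95% limits of agreement mean +/- 1.96 sd.
#'
#' @param pred,obs Aligned numeric vectors, n >= 2.
#' @return A list of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `means`, `diffs`.
#' @export
bland_altman <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  if (length(pred) < 2) stop("Bland-Altman requires at least two pairs")
  d <- pred - obs
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 means = (pred + obs) / 2, diffs = d),
            class = "bland_altman")
}

#' Paired comparison of two predictors
#'
#' Compares per-instance absolute errors of two predictors with a paired
#' t-test, and their therapeutic-category correctness with McNemar's test on
#' the 2x2 correct/incorrect table. The McNemar chi-square statistic uses the
#' continuity correction \eqn{(|b - c| - 1)^2 / (b + c)}; when the discordant
#' count b + c is under 25 the p-value comes from the exact binomial form
#' instead.
#'
#' @param err_a,err_b Aligned per-instance absolute errors of the two
#'   predictors (mg/L).
#' @param correct_a,correct_b Aligned logical vectors: did each predictor
#'   place the instance in the correct therapeutic category?
#' @return A list of class `paired_comparison` with elements `t`
#'   (`mean_diff`, `statistic`, `p`, possibly NA under zero variance) and
#'   `mcnemar` (`b`, `c`, `statistic`, `p`, `method`).
#' @export
paired_tests <- function(err_a, err_b, correct_a, correct_b) {
  if (length(err_a) != length(err_b)) stop("error vectors must be aligned")
  if (length(err_a) < 2) stop("need at least two pairs")
  d <- err_a - err_b
  if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    # (near-)constant differences: the paired t statistic is undefined
    t_res <- list(mean_diff = mean(d), statistic = NA_real_, p = NA_real_)
    if (mean(d) == 0) t_res$p <- 1
  } else {
    tt <- stats::t.test(err_a, err_b, paired = TRUE)
    t_res <- list(mean_diff = mean(d),
                  statistic = unname(tt$statistic), p = tt$p.value)
  }
  b <- sum(correct_a & !correct_b)   # A right, B wrong
  cc <- sum(!correct_a & correct_b)  # A wrong, B right
  n_disc <- b + cc
  stat <- if (n_disc > 0) (abs(b - cc) - 1)^2 / n_disc else NA_real_
  if (n_disc == 0) {
    mc <- list(b = b, c = cc, statistic = NA_real_, p = 1,
               method = "degenerate (no discordant pairs)")
  } else if (n_disc < 25) {
    mc <- list(b = b, c = cc, statistic = stat,
               p = stats::binom.test(b, n_disc, 0.5)$p.value,
               method = "exact binomial")
  } else {
    mc <- list(b = b, c = cc, statistic = stat,
               p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
               method = "continuity-corrected chi-square")
  }
  structure(list(t = t_res, mcnemar = mc), class = "paired_comparison")
}
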