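#' Proximity-to-range reward for a trough value
#'
#' Default reward used by the dose search and the distance-reward analysis:
#' 0 when the trough lies inside the therapeutic range (bounds inclusive) and
#' minus the distance, in mg/L, to the nearest bound otherwise. Always <= 0;
#' alternative reward shapes can be injected wherever a reward function is
#' accepted.
#'
#' @param trough Trough value(s), mg/L.
#' @param lower,upper Therapeutic range bounds, mg/L.
#' @return Numeric reward(s), <= 0.
#' @export
reward_proximity <- function(trough, lower, upper) {
  if (any(lower <= 0) || any(lower >= upper)) stop("invalid therapeutic range")
  -pmax(lower - trough, trough - upper, 0)
}

#' Line search over 250 mg dose adjustments
#'
#' Enumerates candidate changes to the interval dose on a fixed grid
#' (multiples of `step` up to `max_delta` in both directions, clipped so the
#' dose never goes below zero), predicts the trough at each candidate, and
#' returns the candidate maximizing the reward. Ties are broken first by the
#' predicted trough closest to the range midpoint, then by the smallest
#' absolute dose change. The search is exhaustive over the grid, so the
#' result does not depend on evaluation order.
#'
#' @param predict_fn Function mapping a vector of candidate interval doses
#'   (mg) to predicted troughs (mg/L).
#' @param base_dose Actual interval dose, mg.
#' @param lower,upper Therapeutic range bounds, mg/L.
#' @param step Grid increment, mg.
#' @param max_delta Largest total increase or decrease explored, mg.
#' @param reward_fn Reward function `(trough, lower, upper) -> score`;
#'   defaults to [reward_proximity()].
#' @return A list of class `dose_recommendation`: `base_dose`,
#'   `recommended_dose`, `delta`, `predicted_trough`, `reward`, and the full
#'   `trace` data frame (candidate dose, predicted trough, reward).
#' @export
search_dose <- function(predict_fn, base_dose, lower, upper,
                        step = 250, max_delta = 1500,
                        reward_fn = reward_proximity) {
  stopifnot(base_dose >= 0, step > 0, max_delta >= step)
  deltas <- seq(-max_delta, max_delta, by = step)
  deltas <- deltas[base_dose + deltas >= 0]
  doses <- base_dose + deltas
  troughs <- predict_fn(doses)
  if (length(troughs) != length(doses)) {
    stop("predict_fn must return one trough per candidate dose")
  }
  rewards <- reward_fn(troughs, lower, upper)
  mid <- (lower + upper) / 2
  ord <- order(-rewards, abs(troughs - mid), abs(deltas))
  best <- ord[1]
  structure(list(
    base_dose = base_dose,
    recommended_dose = doses[best],
    delta = deltas[best],
    predicted_trough = troughs[best],
    reward = rewards[best],
    trace = data.frame(dose = doses, delta = deltas,
                       predicted_trough = troughs, reward = rewards)
  ), class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf(
    "Dose recommendation: %g mg -> %g mg (delta %+g mg)\n",
    x$base_dose, x$recommended_dose, x$delta))
  cat(sprintf("  predicted trough %.2f mg/L, reward %.3f, %d candidates\n",
              x$predicted_trough, x$reward, nrow(x$trace)))
  invisible(x)
}

# Predicted troughs for one featurized instance under counterfactual interval
# doses: the raw interval-dose skip feature is replaced, re-normalized with
# the model's training statistics, and the model re-run. When
# `adjust_day_dose` is TRUE the prediction-day dose skip feature is scaled by
# the same factor.
counterfactual_predict_fn <- function(model, features, index,
                                      adjust_day_dose = FALSE) {
  stats <- model$stats
  skip_raw <- features$skip_raw[index, ]
  base <- unname(skip_raw["interval_dose_mg"])
  x_seq <- features$X[index, , , drop = FALSE]
  function(doses) {
    k <- length(doses)
    skips <- matrix(rep(skip_raw, each = k), k,
                    dimnames = list(NULL, names(skip_raw)))
    skips[, "interval_dose_mg"] <- doses
    if (adjust_day_dose && base > 0) {
      skips[, "pred_day_dose_mg"] <- skip_raw["pred_day_dose_mg"] * doses / base
    }
    skips <- normalize_skip(skips, stats)
    Xb <- array(x_seq[rep(1, k), , , drop = FALSE],
                c(k, dim(x_seq)[2], dim(x_seq)[3]))
    as.numeric(predict_arrays(model, Xb, skips))
  }
}

#' Recommend an interval dose for one featurized instance
#'
#' Runs the 250 mg line search with the trained model as the predictor,
#' re-predicting the trough for each candidate by updating the interval-dose
#' skip feature (and, optionally, the prediction-day dose) before
#' re-normalizing.
#'
#' @param model A trained `trough_model`.
#' @param features A `trough_features` object.
#' @param index Row index of the instance within `features`.
#' @param adjust_day_dose Also scale the prediction-day dose skip feature
#'   with the candidate dose.
#' @param ... Passed to [search_dose()] (`step`, `max_delta`, `reward_fn`).
#' @return A `dose_recommendation`.
#' @export
recommend_dose <- function(model, features, index, adjust_day_dose = FALSE,
                           ...) {
  check_schema(model, features)
  fn <- counterfactual_predict_fn(model, features, index, adjust_day_dose)
  search_dose(fn, unname(features$skip_raw[index, "interval_dose_mg"]),
              features$range[index, "lower"], features$range[index, "upper"],
              ...)
}

#' Recommend doses for every instance
#'
#' @inheritParams recommend_dose
#' @return Data frame with one row per instance: `base_dose`,
#'   `recommended_dose`, `delta`, `predicted_trough`, `reward`.
#' @export
recommend_all <- function(model, features, adjust_day_dose = FALSE, ...) {
  rows <- lapply(seq_along(features$y), function(i) {
    r <- recommend_dose(model, features, i, adjust_day_dose, ...)
    data.frame(base_dose = r$base_dose, recommended_dose = r$recommended_dose,
               delta = r$delta, predicted_trough = r$predicted_trough,
               reward = r$reward)
  })
  out <- do.call(rbind, rows)
  cbind(features$meta[, c("patient_id", "prediction_day")], out)
}

#' Distance-versus-reward curve
#'
#' For each instance, the distance is the actual interval dose minus the
#' model-recommended dose; the reward is computed on the *measured* trough
#' against its own goal range (a flag switches to the predicted trough).
#' Distances are binned to the nearest `bin_mg`, and each bin reports the
#' mean reward, its standard error, and the count. Empty bins are omitted.
#'
#' @param recommendations Output of [recommend_all()].
#' @param features The matching `trough_features` (provides measured troughs
#'   and ranges).
#' @param bin_mg Bin width in mg.
#' @param use_measured Use measured troughs (default) or the model's
#'   predicted troughs at the actual dose.
#' @param predicted Optional vector of predicted troughs, required when
#'   `use_measured = FALSE`.
#' @param reward_fn Reward function; defaults to [reward_proximity()].
#' @return Data frame of class `reward_curve`: `distance`, `mean_reward`,
#'   `se`, `n`.
#' @export
reward_curve <- function(recommendations, features, bin_mg = 250,
                         use_measured = TRUE, predicted = NULL,
                         reward_fn = reward_proximity) {
  trough <- if (use_measured) features$y else {
    if (is.null(predicted)) stop("predicted troughs required when use_measured = FALSE")
    predicted
  }
  rew <- reward_fn(trough, features$range[, "lower"], features$range[, "upper"])
  dist <- round((recommendations$base_dose - recommendations$recommended_dose) /
                  bin_mg) * bin_mg
  agg <- lapply(split(rew, dist), function(v) {
    c(mean_reward = mean(v),
      se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
      n = length(v))
  })
  out <- data.frame(distance = as.numeric(names(agg)),
                    do.call(rbind, agg), row.names = NULL)
  out <- out[order(out$distance), ]
  class(out) <- c("reward_curve", "data.frame")
  out
}
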