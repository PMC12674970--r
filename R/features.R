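#' Bin timed observations onto an hourly grid
#'
#' Compiles irregular observations into non-overlapping hourly bins, taking
#' the median when a variable has several measurements within one hour. Hour 0
#' is ICU admission; cell (h, v) covers observations with t in [h, h+1).
#'
#' @param observations Data frame with `variable_id`, `t_hours`, `value`.
#' @param n_hours Number of hourly rows in the grid.
#' @param variables Variable ids defining the columns (order preserved);
#'   defaults to those present.
#' @return A list of class `hourly_grid`: `values` (n_hours x V matrix, NA
#'   where unobserved), `mask` (TRUE where a value was observed), `variables`.
#' @export
bin_hourly <- function(observations, n_hours,
                       variables = unique(observations$variable_id)) {
  if (nrow(observations) && any(observations$t_hours < 0)) {
    stop("negative observation timestamps are not allowed")
  }
  values <- matrix(NA_real_, nrow = n_hours, ncol = length(variables),
                   dimnames = list(NULL, variables))
  obs <- observations[observations$variable_id %in% variables &
                        observations$t_hours < n_hours, ]
  if (nrow(obs)) {
    hr <- floor(obs$t_hours)
    agg <- stats::aggregate(value ~ hr + variable_id, data = cbind(obs, hr = hr),
                            FUN = stats::median)
    values[cbind(agg$hr + 1L, match(agg$variable_id, variables))] <- agg$value
  }
  structure(list(values = values, mask = !is.na(values), variables = variables),
            class = "hourly_grid")
}

#' Fill an hourly grid: LOCF up to 24 h, then the training mean
#'
#' Missing cells are filled by the most recent prior value if it is at most
#' `locf_max_h` hours old; any remaining gaps take the training-set mean of
#' that variable. The observation mask is retained for audit, so imputation is
#' idempotent.
#'
#' @param grid An `hourly_grid`.
#' @param means Named numeric vector of per-variable training means.
#' @param locf_max_h Maximum staleness, in hours, for carrying a value forward.
#' @return A complete `hourly_grid` (no NA values), with the original `mask`.
#' @export
impute_grid <- function(grid, means, locf_max_h = 24) {
  stopifnot(inherits(grid, "hourly_grid"))
  absent <- setdiff(grid$variables, names(means))
  if (length(absent)) {
    stop("no training mean available for variable(s): ",
         paste(absent, collapse = ", "))
  }
  values <- grid$values
  n <- nrow(values)
  for (j in seq_along(grid$variables)) {
    col <- values[, j]
    obs_idx <- which(grid$mask[, j])
    if (length(obs_idx)) {
      last_obs <- findInterval(seq_len(n), obs_idx)  # index into obs_idx
      src <- ifelse(last_obs >= 1, obs_idx[pmax(last_obs, 1)], NA_integer_)
      age <- seq_len(n) - src
      fill <- !grid$mask[, j] & !is.na(src) & age <= locf_max_h
      col[fill] <- col[src[fill]]
    }
    col[is.na(col)] <- means[[grid$variables[j]]]
    values[, j] <- col
  }
  grid$values <- values
  grid
}

#' Slope and mean over the trailing 72 h window
#'
#' For each grid variable, computes the mean and the ordinary-least-squares
#' slope (units per hour) of the hourly values over the `window` hours ending
#' at `hour` (exclusive). With less than a full window of history the
#' available prefix is used; with fewer than two points the slope is 0.
#'
#' @param grid A complete (imputed) `hourly_grid`.
#' @param hour Prediction hour (rows 1..hour are history).
#' @param window Window length in hours (default 72).
#' @return A matrix with rows `slope` and `mean`, one column per variable.
#' @export
trend_features <- function(grid, hour, window = 72) {
  stopifnot(inherits(grid, "hourly_grid"), hour >= 1)
  idx <- max(1, hour - window + 1):hour
  vals <- grid$values[idx, , drop = FALSE]
  if (anyNA(vals)) stop("trend_features requires an imputed grid")
  mu <- colMeans(vals)
  if (length(idx) < 2) {
    slope <- rep(0, ncol(vals))
  } else {
    x <- idx - mean(idx)
    slope <- as.numeric(crossprod(x, sweep(vals, 2, mu)) / sum(x^2))
  }
  rbind(slope = slope, mean = mu)
}

transform_skip <- function(skip_raw, log_cols) {
  out <- skip_raw
  for (v in intersect(log_cols, colnames(out))) out[, v] <- log1p(pmax(out[, v], 0))
  out
}

# Raw-unit skip matrix -> model scale (log1p on dose/concentration columns,
# then z-scoring with the training statistics).
normalize_skip <- function(skip_raw, stats) {
  skip_t <- transform_skip(skip_raw, stats$skip_log_cols %||% character(0))
  sweep(sweep(skip_t, 2, stats$skip_mean), 2, stats$skip_sd, "/")
}

# Dose-derived skip features for one instance, in raw units.
skip_dose_features <- function(doses, troughs, prediction_time, target_time) {
  day_doses <- doses$amount_mg[doses$t_start >= prediction_time - 24 &
                                 doses$t_start < prediction_time]
  interval <- doses$amount_mg[doses$t_start > prediction_time &
                                doses$t_start <= target_time]
  before <- doses$t_start[doses$t_start <= prediction_time]
  prior <- troughs[troughs$t_hours < prediction_time, ]
  prior_val <- if (nrow(prior)) prior$value_mg_per_L[which.max(prior$t_hours)] else NA_real_
  c(pred_day_dose_mg = sum(day_doses),
    interval_dose_mg = sum(interval),
    time_since_last_dose_h = if (length(before)) prediction_time - max(before) else 24,
    prior_trough_mg_per_L = prior_val)
}

#' Build model-ready feature tensors for a set of prediction instances
#'
#' Converts each eligible patient-day into the fixed-shape inputs the model
#' consumes: a 24 x F sequence covering the prediction day's 24 hourly steps
#' (time-varying variables after hourly binning and imputation, a derived
#' Cockcroft-Gault creatinine-clearance channel, the vancomycin dose
#' administered in each hour, per-variable 72 h slope and mean, and broadcast
#' static covariates) plus a 4-element dose skip vector
#' (prediction-day total dose, interval dose up to the trough draw, time since
#' the last dose, most recent prior trough).
#'
#' Continuous columns are z-scored with statistics estimated on the training
#' set only; binary flags are left as 0/1. Pass `stats = NULL` to fit the
#' normalization on `instances` (training mode) or the stats returned from a
#' training call to transform validation/test instances without leakage.
#' A missing prior trough is mean-filled and flagged by the broadcast
#' `has_prior_trough` indicator.
#'
#' @param cohort An `icu_cohort`.
#' @param instances A `prediction_instances` data frame.
#' @param stats `NULL` to fit normalization statistics, or a `norm_stats`
#'   object from a previous (training) call.
#' @return A list of class `trough_features`: `X` (n x 24 x F array), `skip`
#'   (n x 4 matrix, normalized), `skip_raw` (raw units), `y`, `range` (n x 2),
#'   `meta` (the instances), `schema`, and `stats`.
#' @export
build_features <- function(cohort, instances, stats = NULL) {
  stopifnot(inherits(cohort, "icu_cohort"))
  if (nrow(instances) == 0) stop("no instances to featurize")
  tv_vars <- names(cohort$config$observation_schedule) %||%
    sort(unique(cohort$observations$variable_id))
  if (!"scr" %in% tv_vars) {
    stop("the feature schema requires an 'scr' observation stream ",
         "(needed for the derived creatinine-clearance channel)")
  }
  comorbid <- intersect(names(cohort$config$comorbidities) %||%
                          c("ckd", "diabetes", "hypertension", "liver_disease",
                            "sepsis"),
                        names(cohort$encounters))
  fitting <- is.null(stats)
  if (fitting) {
    obs_train <- cohort$observations[
      cohort$observations$patient_id %in% unique(instances$patient_id), ]
    impute_means <- vapply(tv_vars, function(v) {
      vals <- obs_train$value[obs_train$variable_id == v]
      if (length(vals)) mean(vals) else 0
    }, numeric(1))
    tr_tr <- cohort$troughs[cohort$troughs$patient_id %in%
                              unique(instances$patient_id), ]
    prior_trough_mean <- if (nrow(tr_tr)) mean(tr_tr$value_mg_per_L) else 10
  } else {
    impute_means <- stats$impute_means
    prior_trough_mean <- stats$prior_trough_mean
  }

  all_vars <- c(tv_vars, "crcl")
  seq_cols <- c(all_vars, "vanc_dose",
                paste0(all_vars, "_slope72"), paste0(all_vars, "_mean72"),
                "age", "sex_male", "weight", "height", "baseline_scr",
                comorbid, "has_prior_trough")
  binary_cols <- c("sex_male", comorbid, "has_prior_trough")
  # Concentration-like quantities are right-skewed and enter the physics
  # multiplicatively; they are log1p-transformed before z-scoring.
  log_cols <- intersect(c("scr", "crcl", "wbc", "scr_mean72", "crcl_mean72",
                          "wbc_mean72", "baseline_scr", "vanc_dose"), seq_cols)
  skip_cols <- c("pred_day_dose_mg", "interval_dose_mg",
                 "time_since_last_dose_h", "prior_trough_mg_per_L")
  skip_log_cols <- c("pred_day_dose_mg", "interval_dose_mg",
                     "prior_trough_mg_per_L")

  n <- nrow(instances)
  X <- array(NA_real_, dim = c(n, 24, length(seq_cols)),
             dimnames = list(NULL, NULL, seq_cols))
  skip_raw <- matrix(NA_real_, n, length(skip_cols),
                     dimnames = list(NULL, skip_cols))
  has_prior <- numeric(n)

  for (pid in unique(instances$patient_id)) {
    rows <- which(instances$patient_id == pid)
    enc <- cohort$encounters[cohort$encounters$patient_id == pid, ]
    if (nrow(enc) == 0) stop("instance references unknown encounter: ", pid)
    obs <- cohort$observations[cohort$observations$patient_id == pid, ]
    doses <- cohort$doses[cohort$doses$patient_id == pid, ]
    troughs <- cohort$troughs[cohort$troughs$patient_id == pid, ]
    n_hours <- max(instances$prediction_time[rows])
    grid <- impute_grid(bin_hourly(obs, n_hours, tv_vars), impute_means)
    crcl <- pmin(cockcroft_gault(enc$age, enc$weight,
                                 pmax(grid$values[, "scr"], 0.1), enc$sex), 180)
    full <- structure(list(values = cbind(grid$values, crcl = crcl),
                           mask = cbind(grid$mask,
                                        crcl = grid$mask[, "scr"]),
                           variables = all_vars), class = "hourly_grid")
    statics <- c(age = enc$age, sex_male = as.numeric(enc$sex == "male"),
                 weight = enc$weight, height = enc$height,
                 baseline_scr = enc$baseline_scr,
                 stats::setNames(as.numeric(enc[comorbid]), comorbid))
    for (r in rows) {
      pt <- instances$prediction_time[r]
      hrs <- (pt - 23):pt  # grid rows for the prediction day
      trend <- trend_features(full, pt)
      sk <- skip_dose_features(doses, troughs, pt, instances$target_time[r])
      has_prior[r] <- as.numeric(!is.na(sk["prior_trough_mg_per_L"]))
      if (is.na(sk["prior_trough_mg_per_L"])) {
        sk["prior_trough_mg_per_L"] <- prior_trough_mean
      }
      skip_raw[r, ] <- sk
      # hourly vancomycin administered during the prediction day (mg)
      dose_hour <- floor(doses$t_start)
      vanc_dose <- vapply((pt - 24):(pt - 1), function(h) {
        sum(doses$amount_mg[dose_hour == h])
      }, numeric(1))
      X[r, , ] <- cbind(full$values[hrs, , drop = FALSE],
                        vanc_dose = vanc_dose,
                        matrix(trend["slope", ], 24, length(all_vars), byrow = TRUE),
                        matrix(trend["mean", ], 24, length(all_vars), byrow = TRUE),
                        matrix(statics, 24, length(statics), byrow = TRUE),
                        has_prior_trough = rep(has_prior[r], 24))
    }
  }

  for (v in log_cols) X[, , v] <- log1p(pmax(X[, , v], 0))
  if (fitting) {
    flat <- matrix(aperm(X, c(2, 1, 3)), ncol = length(seq_cols))
    seq_mean <- colMeans(flat)
    seq_sd <- pmax(apply(flat, 2, stats::sd), 1e-6)
    scaled <- !(seq_cols %in% binary_cols)
    seq_mean[!scaled] <- 0
    seq_sd[!scaled] <- 1
    skip_t <- transform_skip(skip_raw, skip_log_cols)
    skip_mean <- colMeans(skip_t)
    skip_sd <- pmax(apply(skip_t, 2, stats::sd), 1e-6)
    stats <- structure(list(
      impute_means = impute_means, prior_trough_mean = prior_trough_mean,
      seq_mean = stats::setNames(seq_mean, seq_cols),
      seq_sd = stats::setNames(seq_sd, seq_cols),
      skip_mean = stats::setNames(skip_mean, skip_cols),
      skip_sd = stats::setNames(skip_sd, skip_cols),
      scaled = stats::setNames(scaled, seq_cols),
      log_cols = log_cols, skip_log_cols = skip_log_cols
    ), class = "norm_stats")
  }
  for (j in seq_along(seq_cols)) {
    X[, , j] <- (X[, , j] - stats$seq_mean[j]) / stats$seq_sd[j]
  }
  skip <- normalize_skip(skip_raw, stats)

  structure(list(
    X = X, skip = skip, skip_raw = skip_raw,
    y = instances$target_trough,
    range = cbind(lower = instances$range_lower, upper = instances$range_upper),
    meta = instances,
    schema = list(seq_cols = seq_cols, skip_cols = skip_cols,
                  binary_cols = binary_cols),
    stats = stats
  ), class = "trough_features")
}
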