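# Fixture builders: hand-constructed miniature cohorts with known structure.

toy_encounter_row <- function(patient_id, age = 50, sex = "male", weight = 80,
                              height = 175, baseline_scr = 1.0,
                              icu_discharge = 24 * 8, krt_hours = integer(0),
                              cont_infusion_days = integer(0)) {
  data.frame(
    patient_id = patient_id, age = age, sex = sex, weight = weight,
    height = height, ethnicity = "white", baseline_scr = baseline_scr,
    icu_admit = 0, icu_discharge = icu_discharge,
    krt_hours = troughcast:::encode_int_set(list(krt_hours)),
    cont_infusion_days = troughcast:::encode_int_set(list(cont_infusion_days)),
    aki_stage = 0L, aki_peak_ratio = 1,
    ckd = 0L, diabetes = 0L, hypertension = 0L, liver_disease = 0L,
    sepsis = 0L, stringsAsFactors = FALSE
  )
}

toy_doses <- function(patient_id, t_start, amount_mg = 1000, duration_h = 1) {
  data.frame(patient_id = patient_id, t_start = t_start,
             amount_mg = amount_mg, duration_h = duration_h)
}

toy_troughs <- function(patient_id, t_hours, value = 12,
                        lower = 10, upper = 15, pharm = NA_real_) {
  data.frame(patient_id = patient_id, t_hours = t_hours,
             value_mg_per_L = value, range_lower = lower, range_upper = upper,
             pharmacist_prediction = pharm,
             true_clearance_L_h = NA_real_, true_vd_L = NA_real_)
}

toy_scr_obs <- function(patient_id, until_h, value = 1.0, every = 12) {
  t <- seq(1, until_h, by = every)
  data.frame(patient_id = patient_id, variable_id = "scr", t_hours = t,
             value = value)
}

make_cohort <- function(encounters, observations = NULL, doses = NULL,
                        troughs = NULL) {
  empty_obs <- data.frame(patient_id = character(0), variable_id = character(0),
                          t_hours = numeric(0), value = numeric(0))
  empty_doses <- data.frame(patient_id = character(0), t_start = numeric(0),
                            amount_mg = numeric(0), duration_h = numeric(0))
  empty_troughs <- toy_troughs("x", 0)[0, ]
  structure(list(
    encounters = encounters,
    observations = observations %||% empty_obs,
    doses = doses %||% empty_doses,
    troughs = troughs %||% empty_troughs,
    config = NULL, seed = NA
  ), class = "icu_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A fully eligible single-encounter cohort: daily q12h dosing, regular SCr,
# one trough 48 h after the end of each odd prediction day.
eligible_cohort <- function(pid = "A", n_days = 8, dose_mg = 1000,
                            trough_days = c(4, 6), trough_value = 12) {
  dis <- n_days * 24
  dose_t <- seq(6, dis - 6, by = 12)
  tr_t <- (trough_days - 1) * 24 + 6 - 0.5  # just before that day's first dose
  make_cohort(
    toy_encounter_row(pid, icu_discharge = dis),
    observations = toy_scr_obs(pid, dis),
    doses = toy_doses(pid, dose_t, dose_mg),
    troughs = toy_troughs(pid, tr_t, trough_value)
  )
}

bind_cohorts <- function(...) {
  parts <- list(...)
  structure(list(
    encounters = do.call(rbind, lapply(parts, `[[`, "encounters")),
    observations = do.call(rbind, lapply(parts, `[[`, "observations")),
    doses = do.call(rbind, lapply(parts, `[[`, "doses")),
    troughs = do.call(rbind, lapply(parts, `[[`, "troughs")),
    config = NULL, seed = NA
  ), class = "icu_cohort")
}

# Minimal randomized trough_features object for model-level tests that do not
# need the full pipeline.
random_features <- function(n = 20, n_seq = 6, n_skip = 4, seed = 1,
                            y_fun = NULL, n_patients = max(2, n %/% 3)) {
  withr::with_seed(seed, {
    X <- array(stats::rnorm(n * 24 * n_seq), c(n, 24, n_seq))
    seq_cols <- paste0("f", seq_len(n_seq))
    dimnames(X) <- list(NULL, NULL, seq_cols)
    skip_raw <- cbind(
      pred_day_dose_mg = stats::runif(n, 500, 2500),
      interval_dose_mg = stats::runif(n, 1000, 8000),
      time_since_last_dose_h = stats::runif(n, 1, 12),
      prior_trough_mg_per_L = stats::runif(n, 5, 25)
    )[, seq_len(n_skip), drop = FALSE]
    stats_obj <- structure(list(
      impute_means = NULL, prior_trough_mean = 12,
      skip_mean = colMeans(skip_raw),
      skip_sd = pmax(apply(skip_raw, 2, stats::sd), 1e-6),
      skip_log_cols = character(0)
    ), class = "norm_stats")
    skip <- troughcast:::normalize_skip(skip_raw, stats_obj)
    y <- if (is.null(y_fun)) stats::runif(n, 5, 25) else y_fun(X, skip_raw)
    structure(list(
      X = X, skip = skip, skip_raw = skip_raw, y = y,
      range = cbind(lower = rep(10, n), upper = rep(15, n)),
      meta = data.frame(
        patient_id = paste0("P", rep_len(seq_len(n_patients), n)),
        prediction_day = rep(2L, n)
      ),
      schema = list(seq_cols = seq_cols, skip_cols = colnames(skip_raw),
                    binary_cols = character(0)),
      stats = stats_obj
    ), class = "trough_features")
  })
}
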