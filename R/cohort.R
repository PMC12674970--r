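#' Eligibility rules for trough-prediction patient-days
#'
#' Thresholds implementing the cohort filter: adults with at least
#' `min_stay_h` in the ICU; a patient-day is eligible when it lies within the
#' first `max_stay_days` of the stay, has no continuous vancomycin infusion,
#' no kidney replacement therapy on the day or the preceding `krt_lookback_days`,
#' at least one IV vancomycin dose, and a trough measured in the window
#' `trough_window_h` after the end of the day (nominally two days later).
#' Individual rules can be switched off for ablation via `enabled`.
#'
#' @param min_age Minimum age in years.
#' @param min_stay_h Minimum ICU stay in hours.
#' @param max_stay_days Last eligible prediction day (days from admission).
#' @param krt_lookback_days Days before the prediction day in which KRT also
#'   disqualifies.
#' @param trough_window_h Two-element vector: hours after the prediction time
#'   within which the target trough must fall (nominal 48 h).
#' @param enabled Character vector of active rules; defaults to all of
#'   `"age"`, `"min_stay"`, `"max_stay"`, `"continuous_infusion"`, `"krt"`,
#'   `"dose"`, `"trough"`.
#' @return A list of class `eligibility_rules`.
#' @export
eligibility_rules <- function(min_age = 18, min_stay_h = 24, max_stay_days = 14,
                              krt_lookback_days = 7,
                              trough_window_h = c(36, 60),
                              enabled = c("age", "min_stay", "max_stay",
                                          "continuous_infusion", "krt",
                                          "dose", "trough")) {
  stopifnot(length(trough_window_h) == 2, trough_window_h[1] < trough_window_h[2])
  structure(list(min_age = min_age, min_stay_h = min_stay_h,
                 max_stay_days = max_stay_days,
                 krt_lookback_days = krt_lookback_days,
                 trough_window_h = trough_window_h, enabled = enabled),
            class = "eligibility_rules")
}

#' Select eligible patient-days and attach their target troughs
#'
#' Applies the eligibility rules encounter by encounter and day by day. Days
#' are whole 24 h blocks from ICU admission (day 1 covers hours 0-24); the
#' prediction time is the end of the day. Each retained day becomes one
#' prediction instance whose target is the earliest trough falling in the
#' configured window after the prediction time, so one encounter can yield
#' several instances. Encounters missing age or admission/discharge times are
#' skipped with a warning rather than aborting the run.
#'
#' @param cohort An `icu_cohort`.
#' @param rules An [eligibility_rules()] object.
#' @return A data frame of class `prediction_instances` with one row per
#'   eligible patient-day: `patient_id`, `prediction_day`, `prediction_time`,
#'   `target_time`, `target_trough`, `range_lower`, `range_upper`,
#'   `pharmacist_prediction` (NA when absent).
#' @export
select_eligible <- function(cohort, rules = eligibility_rules()) {
  stopifnot(inherits(cohort, "icu_cohort"))
  on_rule <- function(r) r %in% rules$enabled
  out <- list()
  for (i in seq_len(nrow(cohort$encounters))) {
    enc <- cohort$encounters[i, ]
    if (is.na(enc$age) || is.na(enc$icu_admit) || is.na(enc$icu_discharge)) {
      warning(sprintf("skipping encounter %s: missing age or ICU times",
                      enc$patient_id))
      next
    }
    if (on_rule("age") && enc$age < rules$min_age) next
    los <- enc$icu_discharge - enc$icu_admit
    if (on_rule("min_stay") && los < rules$min_stay_h) next

    pid <- enc$patient_id
    doses <- cohort$doses[cohort$doses$patient_id == pid, ]
    troughs <- cohort$troughs[cohort$troughs$patient_id == pid, ]
    if (nrow(doses) == 0 || nrow(troughs) == 0) next
    krt_days <- unique(hour_to_day(decode_int_set(enc$krt_hours)[[1]]))
    cont_days <- decode_int_set(enc$cont_infusion_days)[[1]]

    last_day <- hour_to_day(los)
    for (day in seq_len(last_day)) {
      if (on_rule("max_stay") && day > rules$max_stay_days) next
      if (on_rule("continuous_infusion") && day %in% cont_days) next
      if (on_rule("krt") &&
          any(krt_days >= day - rules$krt_lookback_days & krt_days <= day)) next
      day_lo <- (day - 1) * 24
      day_hi <- day * 24
      if (on_rule("dose") &&
          !any(doses$t_start >= day_lo & doses$t_start < day_hi)) next
      prediction_time <- day_hi
      window <- prediction_time + rules$trough_window_h
      hit <- troughs[troughs$t_hours >= window[1] & troughs$t_hours <= window[2], ]
      if (on_rule("trough") && nrow(hit) == 0) next
      if (nrow(hit) == 0) next  # no target even with the rule disabled
      hit <- hit[order(hit$t_hours), ][1, ]
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, prediction_day = day,
        prediction_time = prediction_time, target_time = hit$t_hours,
        target_trough = hit$value_mg_per_L,
        range_lower = hit$range_lower, range_upper = hit$range_upper,
        pharmacist_prediction = if ("pharmacist_prediction" %in% names(hit))
          hit$pharmacist_prediction else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    patient_id = character(0), prediction_day = integer(0),
    prediction_time = numeric(0), target_time = numeric(0),
    target_trough = numeric(0), range_lower = numeric(0),
    range_upper = numeric(0), pharmacist_prediction = numeric(0)
  )
  rownames(res) <- NULL
  class(res) <- c("prediction_instances", "data.frame")
  res
}

#' Encounter-level train/test split
#'
#' Splits prediction instances into training and test sets at the encounter
#' level: all instances from one patient land on the same side, preventing
#' leakage of within-encounter correlation. Deterministic given `seed`.
#'
#' @param instances A `prediction_instances` data frame.
#' @param fraction Training fraction in (0, 1); honoured to within one
#'   encounter.
#' @param seed Integer seed for the encounter shuffle.
#' @return A list with `train` and `test` instance data frames.
#' @export
split_train_test <- function(instances, fraction = 0.8, seed = 1) {
  if (nrow(instances) == 0) stop("instances must be non-empty")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  ids <- sort(unique(instances$patient_id))
  shuffled <- with_seed(seed, sample(ids))
  n_train <- round(fraction * length(ids))
  n_train <- min(max(n_train, 1L), length(ids) - 1L)
  train_ids <- shuffled[seq_len(n_train)]
  keep_class <- function(x) { class(x) <- class(instances); x }
  list(train = keep_class(instances[instances$patient_id %in% train_ids, ]),
       test = keep_class(instances[!(instances$patient_id %in% train_ids), ]))
}
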