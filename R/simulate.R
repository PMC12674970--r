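#' Configuration for the synthetic ICU cohort generator
#'
#' Returns the full set of simulator parameters with defaults chosen to mimic
#' a mixed medical/surgical ICU population receiving intermittent IV
#' vancomycin: demographics and comorbidity prevalences match typical adult
#' ICU cohorts, stays have a median near 5 days, a configurable fraction of
#' encounters carry kidney replacement therapy, continuous-infusion days or
#' >14-day stays (so the eligibility filter has real work), serum creatinine
#' follows piecewise log-linear acute kidney injury episodes, and troughs are
#' sampled just before a scheduled dose with Gaussian assay/documentation
#' noise on top of the closed-form one-compartment concentration.
#'
#' @param n_encounters Number of ICU encounters to simulate.
#' @param pk One-compartment PK ground truth: `clearance_intercept` (L/h),
#'   `clearance_slope` (unitless, multiplies CrCl expressed in L/h),
#'   `vd_per_kg` (L/kg), `residual_sd` (mg/L noise on measured troughs),
#'   `infusion_duration` (h).
#' @param dosing Dosing-policy parameters: interval `tau` (h), rounding
#'   increment and bounds (mg), and `policy_cl_error_sd`, the log-scale
#'   idiosyncratic error of the prescriber's clearance estimate, and
#'   `hold_threshold` (mg/L above the range upper bound beyond which doses are
#'   held until the level is projected to decay into range). The
#'   prescriber anchors that estimate to the baseline creatinine, so drift in
#'   kidney function (notably AKI) adds a second, observable source of
#'   off-target troughs.
#' @param aki `incidence` of acute kidney injury per encounter and
#'   `stage_probs`, the conditional distribution over stages 1:3.
#' @param ineligible Fractions of encounters forced to carry KRT hours,
#'   continuous-infusion days, stays beyond 14 days, or stays under 24 h.
#' @param observation_schedule Per-variable sampling interval (h) and dropout
#'   probability for the observation streams.
#' @param prob_high_range Probability that a non-septic patient nevertheless
#'   receives the higher 15-20 mg/L goal (septic patients always do).
#' @param pharmacist `bias_slope` (multiplier on the true clearance slope) and
#'   `noise_sd` (mg/L) of the deliberately mis-specified benchmark predictor
#'   whose predictions populate the `pharmacist_prediction` column.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_encounters = 500,
                          pk = list(),
                          dosing = list(),
                          aki = list(),
                          ineligible = list(),
                          observation_schedule = NULL,
                          prob_high_range = 0.1,
                          pharmacist = list()) {
  config <- list(
    n_encounters = n_encounters,
    pk = utils::modifyList(list(
      clearance_intercept = 0.05, clearance_slope = 0.75,
      vd_per_kg = 0.7, residual_sd = 1.0, infusion_duration = 1
    ), pk),
    dosing = utils::modifyList(list(
      tau = 12, dose_round = 250, dose_min = 250, dose_max = 3000,
      policy_cl_error_sd = 0.10, hold_threshold = 5
    ), dosing),
    aki = utils::modifyList(list(
      incidence = 0.4, stage_probs = c(0.67, 0.275, 0.055)
    ), aki),
    ineligible = utils::modifyList(list(
      frac_krt = 0.08, frac_continuous_infusion = 0.05,
      frac_long_stay = 0.12, frac_short_stay = 0.04
    ), ineligible),
    observation_schedule = observation_schedule %||% list(
      scr         = list(interval = 12, dropout = 0.05),
      heart_rate  = list(interval = 1,  dropout = 0.15),
      sbp         = list(interval = 1,  dropout = 0.20),
      temperature = list(interval = 4,  dropout = 0.10),
      wbc         = list(interval = 24, dropout = 0.05)
    ),
    prob_high_range = prob_high_range,
    pharmacist = utils::modifyList(list(bias_slope = 0.9, noise_sd = 1.0),
                                   pharmacist),
    comorbidities = c(ckd = 0.031, diabetes = 0.11, hypertension = 0.148,
                      liver_disease = 0.002, sepsis = 0.163)
  )
  validate_cohort_config(config)
  structure(config, class = "cohort_config")
}

validate_cohort_config <- function(config) {
  if (config$n_encounters < 0) stop("n_encounters must be non-negative")
  pk <- config$pk
  if (any(unlist(pk[c("clearance_intercept", "clearance_slope",
                      "vd_per_kg", "infusion_duration")]) <= 0)) {
    stop("PK parameters must be strictly positive")
  }
  if (pk$residual_sd < 0) stop("residual_sd must be non-negative")
  rates <- c(unlist(config$ineligible), config$aki$incidence,
             config$prob_high_range,
             vapply(config$observation_schedule, `[[`, numeric(1), "dropout"))
  if (any(rates < 0 | rates > 1)) stop("rates and fractions must lie in [0, 1]")
  invisible(config)
}

# Vancomycin clearance (L/h) from creatinine clearance (mL/min): an affine
# link reproducing the well-established CL-CrCl correlation.
clearance_from_crcl <- function(crcl_ml_min, pk) {
  pk$clearance_intercept + pk$clearance_slope * crcl_ml_min * 60 / 1000
}

# Piecewise log-linear hourly SCr trajectory with one optional AKI episode.
scr_trajectory <- function(baseline, n_hours, aki) {
  scr <- rep(baseline, n_hours + 1)
  if (!is.null(aki)) {
    hours <- 0:n_hours
    peak <- baseline * aki$peak_ratio
    rise_end <- aki$onset + aki$rise_h
    plateau_end <- rise_end + aki$plateau_h
    resolve_end <- plateau_end + aki$resolve_h
    in_rise <- hours > aki$onset & hours <= rise_end
    scr[in_rise] <- exp(log(baseline) +
      (log(peak) - log(baseline)) * (hours[in_rise] - aki$onset) / aki$rise_h)
    scr[hours > rise_end & hours <= plateau_end] <- peak
    final <- baseline * aki$recovery_ratio
    in_res <- hours > plateau_end & hours <= resolve_end
    scr[in_res] <- exp(log(peak) +
      (log(final) - log(peak)) * (hours[in_res] - plateau_end) / aki$resolve_h)
    scr[hours > resolve_end] <- final
  }
  scr
}

# Mean CrCl (mL/min) over the `window` hours preceding t, from the hourly
# ground-truth SCr trajectory. CrCl is capped at 180 mL/min.
local_crcl <- function(t, scr_hourly, age, weight, sex, window = 48) {
  idx <- max(0, floor(t - window)):min(length(scr_hourly) - 1, floor(t))
  scr <- mean(scr_hourly[idx + 1])
  min(cockcroft_gault(age, weight, scr, sex), 180)
}

round_dose <- function(dose, dosing) {
  d <- round(dose / dosing$dose_round) * dosing$dose_round
  min(max(d, dosing$dose_min), dosing$dose_max)
}

simulate_encounter <- function(pid, config) {
  pk <- config$pk
  age <- min(max(stats::rnorm(1, 55, 15), 18), 95)
  sex <- if (stats::runif(1) < 0.63) "male" else "female"
  weight <- min(max(stats::rlnorm(1, log(80), 0.25), 40), 180)
  height <- stats::rnorm(1, if (sex == "male") 175 else 162, 8)
  ethnicity <- sample(c("white", "black", "asian", "other"), 1,
                      prob = c(0.52, 0.07, 0.06, 0.35))
  comorbid <- stats::rbinom(length(config$comorbidities), 1,
                            config$comorbidities)
  names(comorbid) <- names(config$comorbidities)
  baseline_scr <- min(max(stats::rlnorm(1, log(0.63), 0.35), 0.3), 3)

  inel <- config$ineligible
  stay_class <- sample(c("short", "long", "normal"), 1,
    prob = c(inel$frac_short_stay, inel$frac_long_stay,
             1 - inel$frac_short_stay - inel$frac_long_stay))
  los <- switch(stay_class,
    short  = stats::runif(1, 16, 23),
    long   = stats::runif(1, 15 * 24, 21 * 24),
    normal = min(max(stats::rlnorm(1, log(4.9), 0.55), 1.2), 13.8) * 24)
  n_hours <- ceiling(los)

  aki <- NULL
  if (stats::runif(1) < config$aki$incidence && los > 72) {
    stage <- sample(1:3, 1, prob = config$aki$stage_probs)
    peak_ratio <- switch(stage, stats::runif(1, 1.5, 1.99),
                         stats::runif(1, 2.0, 2.99), stats::runif(1, 3.0, 4.5))
    aki <- list(onset = stats::runif(1, 12, los * 0.5),
                peak_ratio = peak_ratio,
                rise_h = stats::runif(1, 24, 48),
                plateau_h = stats::runif(1, 12, 24),
                resolve_h = stats::runif(1, 48, 96),
                recovery_ratio = stats::runif(1, 1.0, 1.2))
  }
  scr_hourly <- scr_trajectory(baseline_scr, n_hours, aki)

  krt_hours <- integer(0)
  if (stats::runif(1) < inel$frac_krt && los > 48) {
    krt_start_day <- sample(seq_len(max(1L, hour_to_day(los) - 2L)), 1)
    krt_days <- krt_start_day:min(krt_start_day + sample(0:2, 1), hour_to_day(los))
    krt_hours <- as.integer(unlist(lapply(krt_days, function(d) ((d - 1) * 24):(d * 24 - 1))))
    krt_hours <- krt_hours[krt_hours <= los]
  }
  cont_days <- integer(0)
  if (stats::runif(1) < inel$frac_continuous_infusion && los > 48) {
    cont_days <- sort(sample(seq_len(hour_to_day(los)),
                             min(sample(1:2, 1), hour_to_day(los))))
  }

  vd <- pk$vd_per_kg * weight
  # Severe infections get the higher trough goal; a small random fraction of
  # other patients do too, mirroring indication-driven goal selection.
  range_high <- comorbid[["sepsis"]] == 1 || stats::runif(1) < config$prob_high_range
  rng <- if (range_high) c(15, 20) else c(10, 15)
  target_mid <- mean(rng)

  # The prescriber doses against kidney function estimated from the BASELINE
  # creatinine (plus a small idiosyncratic error); the true clearance follows
  # the current creatinine. The gap between the two - largest around AKI
  # onset and resolution - is the observable, learnable source of
  # off-target troughs.
  cl_policy <- clearance_from_crcl(
    min(cockcroft_gault(age, weight, baseline_scr, sex), 180), pk
  ) * stats::rlnorm(1, 0, config$dosing$policy_cl_error_sd)
  unit_trough <- steady_state_trough(cl_policy, vd, 1000, config$dosing$tau,
                                     pk$infusion_duration)
  amount <- round_dose(1000 * target_mid / unit_trough, config$dosing)

  first_dose <- stats::runif(1, 2, 8)
  dose_times <- seq(first_dose, max(first_dose, los - 1), by = config$dosing$tau)
  trough_days <- if (hour_to_day(los) >= 3) seq(3, hour_to_day(los), by = 2) else integer(0)

  doses <- list(); troughs <- list()
  pending <- lapply(trough_days, function(day) {
    day_doses <- dose_times[hour_to_day(dose_times) == day]
    if (length(day_doses) == 0) return(NULL)
    list(t = day_doses[1] - stats::runif(1, 0, 1), day = day)
  })
  pending <- Filter(Negate(is.null), pending)
  pi <- 1L
  hold_until <- 0
  for (td in dose_times) {
    while (pi <= length(pending) && pending[[pi]]$t < td) {
      tt <- pending[[pi]]$t
      dose_df <- do.call(rbind, doses)
      cl_true <- clearance_from_crcl(
        local_crcl(tt, scr_hourly, age, weight, sex), pk)
      conc <- concentration_at(cl_true, vd, dose_df, tt)
      value <- conc + stats::rnorm(1, 0, pk$residual_sd)
      if (pk$residual_sd > 0) value <- max(value, 0.1)
      cl_pharm <- pk$clearance_intercept +
        config$pharmacist$bias_slope * pk$clearance_slope *
        local_crcl(tt, scr_hourly, age, weight, sex) * 60 / 1000
      pharm <- max(concentration_at(cl_pharm, vd, dose_df, tt) +
                     stats::rnorm(1, 0, config$pharmacist$noise_sd), 0.1)
      troughs[[length(troughs) + 1L]] <- data.frame(
        patient_id = pid, t_hours = tt, value_mg_per_L = value,
        range_lower = rng[1], range_upper = rng[2],
        pharmacist_prediction = pharm,
        true_clearance_L_h = cl_true, true_vd_L = vd
      )
      # TDM-style retitration toward the mid-range target from the next dose
      # on; markedly supratherapeutic troughs additionally trigger a dose hold
      # (doses withheld until the projected level decays back to the upper
      # bound), as in routine practice
      amount <- round_dose(amount * target_mid / max(value, 1), config$dosing)
      if (value > rng[2] + config$dosing$hold_threshold) {
        k_now <- cl_true / vd
        hold_until <- tt + log(value / rng[2]) / k_now
      }
      pi <- pi + 1L
    }
    if (td < hold_until) next
    doses[[length(doses) + 1L]] <- data.frame(
      patient_id = pid, t_start = td, amount_mg = amount,
      duration_h = pk$infusion_duration
    )
  }

  obs <- list()
  for (v in names(config$observation_schedule)) {
    sched <- config$observation_schedule[[v]]
    times <- seq(stats::runif(1, 0, min(sched$interval, los / 2)), los,
                 by = sched$interval)
    times <- times[stats::runif(length(times)) >= sched$dropout]
    if (length(times) == 0) next
    values <- switch(v,
      scr = scr_hourly[pmin(floor(times), n_hours) + 1] *
        stats::rlnorm(length(times), 0, 0.03),
      heart_rate = stats::rnorm(length(times),
        80 + 15 * comorbid[["sepsis"]], 8),
      sbp = stats::rnorm(length(times), 120 - 10 * comorbid[["sepsis"]], 12),
      temperature = stats::rnorm(length(times),
        36.8 + 0.7 * comorbid[["sepsis"]], 0.3),
      wbc = stats::rlnorm(length(times),
        log(9 + 4 * comorbid[["sepsis"]]), 0.2),
      stats::rnorm(length(times), 0, 1))
    obs[[v]] <- data.frame(patient_id = pid, variable_id = v,
                           t_hours = times, value = values)
  }

  enc <- data.frame(
    patient_id = pid, age = age, sex = sex, weight = weight, height = height,
    ethnicity = ethnicity, baseline_scr = baseline_scr,
    icu_admit = 0, icu_discharge = los,
    krt_hours = encode_int_set(list(krt_hours)),
    cont_infusion_days = encode_int_set(list(cont_days)),
    aki_stage = if (is.null(aki)) 0L else
      classify_aki_stage(baseline_scr * aki$peak_ratio, baseline_scr),
    aki_peak_ratio = if (is.null(aki)) 1 else aki$peak_ratio,
    stringsAsFactors = FALSE
  )
  enc <- cbind(enc, as.data.frame(as.list(comorbid)))

  list(encounter = enc,
       observations = if (length(obs)) do.call(rbind, obs) else NULL,
       doses = if (length(doses)) do.call(rbind, doses) else NULL,
       troughs = if (length(troughs)) do.call(rbind, troughs) else NULL)
}

#' Generate a synthetic ICU vancomycin cohort
#'
#' Simulates `config$n_encounters` ICU encounters with covariate-driven
#' vancomycin clearance, intermittent IV dosing titrated by an imperfect
#' prescriber, irregularly sampled labs and vitals, piecewise log-linear
#' creatinine trajectories with acute kidney injury episodes, and trough
#' measurements equal to the closed-form one-compartment concentration plus
#' Gaussian noise. Output is byte-identical for a fixed `(config, seed)`.
#'
#' Troughs carry the simulator ground truth (`true_clearance_L_h`,
#' `true_vd_L`) so that generated values can be validated against
#' [concentration_at()]; these columns are never model inputs.
#'
#' @param config A [cohort_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `icu_cohort`: a list with data frames
#'   `encounters`, `observations`, `doses`, `troughs`, plus `config` and
#'   `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  validate_cohort_config(config)
  empty <- empty_cohort(config, seed)
  if (config$n_encounters == 0) return(empty)
  sims <- with_seed(seed, {
    lapply(seq_len(config$n_encounters), function(i) {
      simulate_encounter(sprintf("P%04d", i), config)
    })
  })
  bind <- function(field, fallback) {
    parts <- Filter(Negate(is.null), lapply(sims, `[[`, field))
    if (length(parts) == 0) return(fallback)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  }
  structure(list(
    encounters = bind("encounter", empty$encounters),
    observations = bind("observations", empty$observations),
    doses = bind("doses", empty$doses),
    troughs = bind("troughs", empty$troughs),
    config = config, seed = seed
  ), class = "icu_cohort")
}

empty_cohort <- function(config, seed) {
  enc <- data.frame(
    patient_id = character(0), age = numeric(0), sex = character(0),
    weight = numeric(0), height = numeric(0), ethnicity = character(0),
    baseline_scr = numeric(0), icu_admit = numeric(0),
    icu_discharge = numeric(0), krt_hours = character(0),
    cont_infusion_days = character(0), aki_stage = integer(0),
    aki_peak_ratio = numeric(0), stringsAsFactors = FALSE
  )
  for (nm in names(config$comorbidities)) enc[[nm]] <- integer(0)
  structure(list(
    encounters = enc,
    observations = data.frame(patient_id = character(0),
                              variable_id = character(0),
                              t_hours = numeric(0), value = numeric(0)),
    doses = data.frame(patient_id = character(0), t_start = numeric(0),
                       amount_mg = numeric(0), duration_h = numeric(0)),
    troughs = data.frame(patient_id = character(0), t_hours = numeric(0),
                         value_mg_per_L = numeric(0), range_lower = numeric(0),
                         range_upper = numeric(0),
                         pharmacist_prediction = numeric(0),
                         true_clearance_L_h = numeric(0),
                         true_vd_L = numeric(0)),
    config = config, seed = seed
  ), class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat("Synthetic ICU vancomycin cohort\n")
  cat(sprintf("  encounters:   %d\n", nrow(x$encounters)))
  cat(sprintf("  observations: %d\n", nrow(x$observations)))
  cat(sprintf("  doses:        %d\n", nrow(x$doses)))
  cat(sprintf("  troughs:      %d\n", nrow(x$troughs)))
  cat(sprintf("  seed:         %s\n", x$seed))
  invisible(x)
}
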