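#' Cockcroft-Gault creatinine clearance
#'
#' Estimates creatinine clearance (mL/min) from age, actual body weight, serum
#' creatinine and sex. This is the kidney-function driver used throughout the
#' simulator and the feature pipeline: vancomycin is cleared almost entirely by
#' the kidney, so CrCl is the covariate that moves its clearance.
#'
#' @param age Age in years (> 0).
#' @param weight Actual body weight in kg (> 0).
#' @param scr Serum creatinine in mg/dL (> 0).
#' @param sex `"male"` or `"female"`; females receive the standard 0.85 factor.
#' @return Creatinine clearance in mL/min. Vectorized over all arguments.
#' @examples
#' cockcroft_gault(40, 72, 1.0, "male")   # 100
#' cockcroft_gault(40, 72, 1.0, "female") # 85
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  sex <- match_sex(sex)
  if (any(!is.finite(age)) || any(age <= 0)) stop("age must be positive and finite")
  if (any(!is.finite(weight)) || any(weight <= 0)) stop("weight must be positive and finite")
  if (any(!is.finite(scr)) || any(scr <= 0)) stop("scr must be positive and finite")
  crcl <- (140 - age) * weight / (72 * scr)
  crcl * ifelse(sex == "female", 0.85, 1)
}

match_sex <- function(sex) {
  sex <- as.character(sex)
  ok <- sex %in% c("male", "female")
  if (!all(ok)) stop("sex must be 'male' or 'female'")
  sex
}

#' One-compartment concentration under intermittent IV infusions
#'
#' Closed-form superposition of zero-order infusions eliminated first-order
#' from a single compartment. For one dose D infused over T hours into volume
#' V with elimination rate k = CL/V, the concentration is
#' \eqn{C(t) = D/(T V k) (1 - e^{-k t})} during the infusion and decays as
#' \eqn{C(T) e^{-k (t - T)}} afterwards; multiple doses superpose linearly.
#' This is the noise-free ground truth behind every simulated trough.
#'
#' @param clearance Vancomycin clearance in L/h (> 0).
#' @param vd Volume of distribution in L (> 0).
#' @param doses Data frame with columns `t_start` (h), `amount_mg`,
#'   `duration_h`, or an empty data frame / NULL for no drug.
#' @param t Time in hours from the reference origin (vectorized, >= 0).
#' @return Concentration in mg/L at each `t`.
#' @export
concentration_at <- function(clearance, vd, doses, t) {
  if (!is.finite(clearance) || clearance <= 0) stop("clearance must be positive")
  if (!is.finite(vd) || vd <= 0) stop("vd must be positive")
  if (any(t < 0)) stop("t must be non-negative")
  k <- clearance / vd
  conc <- numeric(length(t))
  if (is.null(doses) || nrow(doses) == 0L) return(conc)
  stopifnot(all(doses$amount_mg > 0), all(doses$duration_h > 0))
  for (i in seq_len(nrow(doses))) {
    t0 <- doses$t_start[i]
    dur <- doses$duration_h[i]
    rate_term <- doses$amount_mg[i] / (dur * vd * k)
    el <- t - t0
    during <- el >= 0 & el <= dur
    after <- el > dur
    conc[during] <- conc[during] + rate_term * (1 - exp(-k * el[during]))
    conc[after] <- conc[after] +
      rate_term * (1 - exp(-k * dur)) * exp(-k * (el[after] - dur))
  }
  conc
}

#' Steady-state trough for a repeated intermittent infusion
#'
#' Trough concentration at the end of the dosing interval once accumulation
#' has equilibrated: the single-dose trough divided by the accumulation factor
#' \eqn{1 - e^{-k \tau}}.
#'
#' @param clearance Clearance in L/h.
#' @param vd Volume of distribution in L.
#' @param dose Dose per administration in mg.
#' @param tau Dosing interval in h; must exceed `infusion_duration`.
#' @param infusion_duration Infusion length in h (default 1).
#' @return Steady-state trough in mg/L.
#' @export
steady_state_trough <- function(clearance, vd, dose, tau, infusion_duration = 1) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (tau <= infusion_duration) stop("tau must exceed the infusion duration")
  single <- concentration_at(
    clearance, vd,
    data.frame(t_start = 0, amount_mg = dose, duration_h = infusion_duration),
    tau
  )
  k <- clearance / vd
  single / (1 - exp(-k * tau))
}

#' KDIGO-style AKI stage from the peak-to-baseline creatinine ratio
#'
#' Stages acute kidney injury by the ratio of peak to baseline serum
#' creatinine: ratio >= 3 is stage 3, >= 2 stage 2, >= 1.5 stage 1, else 0.
#'
#' @param peak_scr Peak serum creatinine in mg/dL (> 0).
#' @param baseline_scr Baseline serum creatinine in mg/dL (> 0).
#' @return Integer stage in 0:3. Vectorized.
#' @export
classify_aki_stage <- function(peak_scr, baseline_scr) {
  if (any(peak_scr <= 0) || any(baseline_scr <= 0)) {
    stop("creatinine values must be positive")
  }
  ratio <- peak_scr / baseline_scr
  ifelse(ratio >= 3, 3L, ifelse(ratio >= 2, 2L, ifelse(ratio >= 1.5, 1L, 0L)))
}
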