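obs_df <- function(t, value, var = "x") {
  data.frame(patient_id = "A", variable_id = var, t_hours = t, value = value)
}

test_that("hourly binning takes the within-hour median and flags gaps", {
  g <- bin_hourly(obs_df(c(0.2, 0.5, 0.9), c(10, 14, 12)), n_hours = 2)
  expect_equal(unname(g$values[1, "x"]), 12)        # median of three
  expect_false(g$mask[2, "x"])
  g2 <- bin_hourly(obs_df(c(0.1, 0.6), c(10, 14)), n_hours = 1)
  expect_equal(unname(g2$values[1, "x"]), 12)       # even count: mean of middle two
  g3 <- bin_hourly(obs_df(3.5, 7), n_hours = 5)
  expect_true(g3$mask[4, "x"])   # hour 3 observed
  expect_false(g3$mask[1, "x"])
  expect_error(bin_hourly(obs_df(-0.5, 1), 4), "negative")
})

test_that("a stream with one value per hour is reproduced exactly", {
  v <- stats::rnorm(24)
  g <- bin_hourly(obs_df(0:23 + 0.5, v), n_hours = 24)
  expect_equal(unname(g$values[, "x"]), v)
  expect_true(all(g$mask))
})

test_that("imputation carries forward for 24 h then falls back to the mean", {
  vals <- rep(NA_real_, 40); vals[6] <- 7  # observed at hour 5
  g <- structure(list(values = matrix(vals, ncol = 1,
                                      dimnames = list(NULL, "x")),
                      mask = matrix(!is.na(vals), ncol = 1,
                                    dimnames = list(NULL, "x")),
                      variables = "x"), class = "hourly_grid")
  out <- impute_grid(g, means = c(x = 99))
  expect_equal(unname(out$values[7:30, 1]), rep(7, 24))   # hours 6-29 carried
  expect_equal(unname(out$values[31:40, 1]), rep(99, 10)) # hour 30+: mean
  expect_equal(unname(out$values[1:5, 1]), rep(99, 5))    # before first obs
  # idempotence: re-imputing the completed grid changes nothing
  expect_equal(impute_grid(out, means = c(x = 99)), out)
  expect_error(impute_grid(g, means = c(other = 1)), "x")
})

test_that("a fully observed series passes through imputation unchanged", {
  g <- bin_hourly(obs_df(0:9 + 0.1, 1:10), n_hours = 10)
  out <- impute_grid(g, means = c(x = 0))
  expect_equal(out$values, g$values)
})

test_that("trend features recover slope and mean of simple series", {
  mk <- function(v) structure(list(
    values = matrix(v, ncol = 1, dimnames = list(NULL, "x")),
    mask = matrix(TRUE, length(v), 1), variables = "x"), class = "hourly_grid")
  tf <- trend_features(mk(1:80), hour = 80, window = 72)
  expect_equal(unname(tf["slope", 1]), 1)
  expect_equal(unname(tf["mean", 1]), mean(9:80))
  tf2 <- trend_features(mk(rep(4.2, 80)), hour = 80)
  expect_equal(unname(tf2["slope", 1]), 0)
  expect_equal(unname(tf2["mean", 1]), 4.2)
  tf3 <- trend_features(mk(0:71 + 0.0), hour = 72, window = 72)
  expect_equal(unname(tf3["mean", 1]), 35.5)
  # one point of history: slope 0 by convention
  tf4 <- trend_features(mk(c(3, rep(NA, 0))), hour = 1)
  expect_equal(unname(tf4["slope", 1]), 0)
})

test_that("skip features sum doses over the defined windows", {
  co <- eligible_cohort("A", trough_days = 5)
  co$doses <- toy_doses("A", c(32, 56), 1000)   # prediction-day hour 8, next day
  inst <- data.frame(patient_id = "A", prediction_day = 2,
                     prediction_time = 48, target_time = 101.5,
                     target_trough = 12, range_lower = 10, range_upper = 15,
                     pharmacist_prediction = NA_real_)
  sk <- troughcast:::skip_dose_features(co$doses, co$troughs, 48, 101.5)
  expect_equal(unname(sk["pred_day_dose_mg"]), 1000)
  expect_equal(unname(sk["interval_dose_mg"]), 1000)
  expect_equal(unname(sk["time_since_last_dose_h"]), 48 - 32)
})

test_that("feature tensors have the fixed shape and no missing values", {
  co <- generate_cohort(cohort_config(n_encounters = 25), seed = 6)
  inst <- select_eligible(co)
  sp <- split_train_test(inst, 0.7, seed = 1)
  ft <- build_features(co, sp$train)
  fe <- build_features(co, sp$test, stats = ft$stats)
  expect_equal(dim(ft$X)[2:3], c(24, length(ft$schema$seq_cols)))
  expect_equal(dim(fe$X)[3], dim(ft$X)[3])
  expect_false(anyNA(ft$X)); expect_false(anyNA(ft$skip))
  expect_false(anyNA(fe$X)); expect_false(anyNA(fe$skip))
  expect_equal(nrow(ft$X), nrow(sp$train))
})

test_that("normalization statistics come from the training split only", {
  co <- generate_cohort(cohort_config(n_encounters = 25), seed = 6)
  inst <- select_eligible(co)
  sp <- split_train_test(inst, 0.7, seed = 1)
  ft <- build_features(co, sp$train)
  fe <- build_features(co, sp$test, stats = ft$stats)
  expect_identical(fe$stats, ft$stats)
  # training features are centred; test features generally are not
  flat <- matrix(aperm(ft$X, c(2, 1, 3)), ncol = dim(ft$X)[3])
  scaled <- ft$stats$scaled
  expect_true(all(abs(colMeans(flat)[scaled]) < 1e-8))
  # perturbing the test split must not alter the training statistics
  ft2 <- build_features(co, sp$train)
  expect_identical(ft2$stats, ft$stats)
})

test_that("constant inputs z-score to zero and flags stay binary", {
  co <- eligible_cohort("A", trough_days = 5)
  co <- bind_cohorts(co, eligible_cohort("B", trough_days = 5))
  inst <- select_eligible(co)
  ft <- build_features(co, inst)
  # scr constant 1.0 across both encounters: z-scored channel is exactly 0
  expect_true(all(abs(ft$X[, , "scr"]) < 1e-9))
  expect_true(all(ft$X[, , "has_prior_trough"] %in% c(0, 1)))
})

test_that("a missing prior trough is mean-filled and flagged", {
  co <- eligible_cohort("A", n_days = 10, trough_days = c(5, 8))
  inst <- select_eligible(co)  # prediction days 2 and 5
  ft <- build_features(co, inst)
  first <- which(inst$prediction_day == 2)
  later <- which(inst$prediction_day == 5)
  expect_equal(unname(ft$X[first, 1, "has_prior_trough"]), 0)
  expect_equal(unname(ft$X[later, 1, "has_prior_trough"]), 1)
  expect_equal(unname(ft$skip_raw[first, "prior_trough_mg_per_L"]),
               ft$stats$prior_trough_mean)
  expect_equal(unname(ft$skip_raw[later, "prior_trough_mg_per_L"]), 12)
})

test_that("featurizing an instance without its encounter fails loudly", {
  co <- eligible_cohort("A", trough_days = 5)
  inst <- select_eligible(co)
  inst$patient_id <- "MISSING"
  expect_error(build_features(co, inst), "unknown encounter")
})
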