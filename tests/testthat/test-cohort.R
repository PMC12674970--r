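# Hand-enumerable eligibility fixtures. The reference cohort (helper
# `eligible_cohort`) doses q12h from hour 6; a trough just before the first
# dose of day d sits at t = (d-1)*24 + 5.5, i.e. 53.5 h after the end of
# prediction day d-3 (inside the 36-60 h target window).

test_that("a toy three-encounter cohort yields exactly the hand-derived instances", {
  a <- eligible_cohort("A", trough_days = 5)          # eligible, one trough
  b <- eligible_cohort("B", trough_days = 5)          # KRT on the prediction day
  b$encounters$krt_hours <- troughcast:::encode_int_set(list(25:47))
  c <- eligible_cohort("C", trough_days = 5)          # no dose on prediction day
  c$doses <- c$doses[troughcast:::hour_to_day(c$doses$t_start) != 2, ]
  inst <- select_eligible(bind_cohorts(a, b, c))
  expect_equal(inst$patient_id[inst$prediction_day == 2], "A")
  expect_false("B" %in% inst$patient_id[inst$prediction_day == 2])
  expect_false("C" %in% inst$patient_id[inst$prediction_day == 2])
})

test_that("each eligibility rule excludes exactly its targeted encounter", {
  base <- function(pid) eligible_cohort(pid, trough_days = 5)

  ok <- base("OK")

  under18 <- base("KID"); under18$encounters$age <- 16

  short <- base("SHORT")  # 20 h stay: below the 24 h floor
  short$encounters$icu_discharge <- 20
  short$doses <- short$doses[short$doses$t_start < 20, ]
  short$troughs <- short$troughs[0, ]

  late <- eligible_cohort("LATE", n_days = 18, trough_days = 18)
  late$doses <- late$doses[troughcast:::hour_to_day(late$doses$t_start) >= 15, ]

  krt_recent <- base("KRT7")  # KRT 5 days before the prediction day
  krt_recent$encounters$krt_hours <- troughcast:::encode_int_set(list(0:10))

  cont <- base("CONT")
  cont$encounters$cont_infusion_days <- troughcast:::encode_int_set(list(2L))

  no_trough <- base("NOTR"); no_trough$troughs <- no_trough$troughs[0, ]

  inst <- select_eligible(bind_cohorts(ok, under18, short, late, krt_recent,
                                       cont, no_trough))
  expect_setequal(unique(inst$patient_id), "OK")
})

test_that("the KRT lookback spares events older than the window", {
  old_krt <- eligible_cohort("OLDKRT", n_days = 12, trough_days = 12)
  # KRT on day 1; prediction day 9 starts more than 7 days later
  old_krt$encounters$krt_hours <- troughcast:::encode_int_set(list(0:10))
  inst <- select_eligible(old_krt)
  expect_equal(inst$prediction_day, 9)
})

test_that("instance counts decrease monotonically as rules are enabled", {
  co <- generate_cohort(cohort_config(n_encounters = 60), seed = 7)
  all_rules <- c("age", "min_stay", "max_stay", "continuous_infusion", "krt",
                 "dose", "trough")
  counts <- vapply(seq_along(all_rules), function(k) {
    nrow(select_eligible(co, eligibility_rules(enabled = all_rules[seq_len(k)])))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("instances respect the 36-60 h target window and dose requirement", {
  co <- generate_cohort(cohort_config(n_encounters = 40), seed = 8)
  inst <- select_eligible(co)
  expect_gt(nrow(inst), 0)
  lag <- inst$target_time - inst$prediction_time
  expect_true(all(lag >= 36 & lag <= 60))
  for (i in seq_len(nrow(inst))) {
    d <- co$doses[co$doses$patient_id == inst$patient_id[i], ]
    expect_true(any(d$t_start >= inst$prediction_time[i] - 24 &
                      d$t_start < inst$prediction_time[i]))
  }
})

test_that("the encounter-level split is disjoint, exhaustive and seeded", {
  co <- generate_cohort(cohort_config(n_encounters = 40), seed = 3)
  inst <- select_eligible(co)
  sp1 <- split_train_test(inst, 0.8, seed = 7)
  sp2 <- split_train_test(inst, 0.8, seed = 7)
  expect_identical(sp1$train, sp2$train)
  tr_ids <- unique(sp1$train$patient_id)
  te_ids <- unique(sp1$test$patient_id)
  expect_length(intersect(tr_ids, te_ids), 0)
  expect_setequal(c(tr_ids, te_ids), unique(inst$patient_id))
  n_ids <- length(unique(inst$patient_id))
  expect_lte(abs(length(tr_ids) - round(0.8 * n_ids)), 1)
  expect_error(split_train_test(inst, 1.2, 1), "fraction")
  expect_error(split_train_test(inst[0, ], 0.8, 1), "non-empty")
})

test_that("all instances of one encounter land on the same side of the split", {
  co <- eligible_cohort("A", n_days = 10, trough_days = c(4, 6, 8))
  co <- bind_cohorts(co, eligible_cohort("B"), eligible_cohort("C"))
  inst <- select_eligible(co)
  expect_gte(sum(inst$patient_id == "A"), 3)
  sp <- split_train_test(inst, 0.5, seed = 1)
  a_side <- c("A" %in% sp$train$patient_id, "A" %in% sp$test$patient_id)
  expect_equal(sum(a_side), 1)
})

test_that("encounters with missing core fields are skipped with a warning", {
  bad <- eligible_cohort("BAD")
  bad$encounters$age <- NA_real_
  expect_warning(inst <- select_eligible(bind_cohorts(bad, eligible_cohort("G"))),
                 "missing age")
  expect_setequal(unique(inst$patient_id), "G")
})
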