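# Independent brute-force oracle for the line search: evaluate every
# admissible candidate and apply the documented selection rule directly.
brute_force_best <- function(predict_fn, base_dose, lower, upper,
                             step = 250, max_delta = 1500) {
  deltas <- seq(-max_delta, max_delta, by = step)
  deltas <- deltas[base_dose + deltas >= 0]
  troughs <- predict_fn(base_dose + deltas)
  rewards <- reward_proximity(troughs, lower, upper)
  mid <- (lower + upper) / 2
  best <- which(rewards == max(rewards))
  best <- best[abs(troughs[best] - mid) == min(abs(troughs[best] - mid))]
  best <- best[which.min(abs(deltas[best]))]
  list(delta = deltas[best], dose = base_dose + deltas[best],
       trough = troughs[best])
}

test_that("the proximity reward is zero in range and linear outside", {
  expect_equal(reward_proximity(12, 10, 15), 0)
  expect_equal(reward_proximity(8, 10, 15), -2)
  expect_equal(reward_proximity(17, 10, 15), -2)
  expect_equal(reward_proximity(c(10, 15), 10, 15), c(0, 0))  # bounds inclusive
  expect_true(all(reward_proximity(seq(0, 40, 0.5), 10, 15) <= 0))
  expect_error(reward_proximity(12, 15, 10), "range")
})

test_that("the line search reproduces hand-enumerated stub cases", {
  # +1 mg/L per +250 mg from 8.0: deltas +500..+1500 land in 10-15;
  # 12.0 and 13.0 tie on midpoint distance, smaller |delta| wins
  up <- function(doses) 8 + (doses - 2000) / 250
  r <- search_dose(up, 2000, 10, 15)
  expect_equal(r$delta, 1000)
  expect_equal(r$predicted_trough, 12)
  expect_equal(r$recommended_dose, 3000)
  expect_equal(nrow(r$trace), 13)

  # 22.0 falling 1 mg/L per -250 mg: cap binds at -1500, still above range
  down <- function(doses) 22 + (doses - 3000) / 250
  r2 <- search_dose(down, 3000, 10, 15)
  expect_equal(r2$delta, -1500)
  expect_equal(r2$predicted_trough, 16)
  expect_equal(r2$reward, -1)

  # zero floor: base dose 500 admits deltas -500 ... +1500 only
  r3 <- search_dose(function(d) rep(20, length(d)), 500, 10, 15)
  expect_equal(sort(r3$trace$delta), seq(-500, 1500, by = 250))
  expect_true(all(r3$trace$dose >= 0))
})

test_that("the search equals brute-force enumeration for randomized stub predictors", {
  withr::with_seed(123, {
    for (i in 1:120) {
      base <- sample(seq(0, 4000, 250), 1)
      lower <- sample(c(10, 15), 1); upper <- lower + 5
      a <- runif(1, -10, 30); b <- runif(1, -8, 8) / 1000
      curv <- runif(1, -1, 1) / 1e6
      fn <- function(d) a + b * d + curv * d^2
      got <- search_dose(fn, base, lower, upper)
      want <- brute_force_best(fn, base, lower, upper)
      expect_equal(got$delta, want$delta)
      expect_equal(got$predicted_trough, want$trough)
    }
  })
})

test_that("with a monotone predictor the recommendation never loses reward", {
  withr::with_seed(9, {
    for (i in 1:20) {
      base <- sample(seq(250, 4000, 250), 1)
      slope <- runif(1, 0.5, 6) / 1000
      icpt <- runif(1, -5, 20)
      fn <- function(d) icpt + slope * d
      r <- search_dose(fn, base, 10, 15)
      expect_gte(r$reward, reward_proximity(fn(base), 10, 15))
    }
  })
})

test_that("model-backed recommendations move the interval-dose feature only", {
  f <- random_features(6, 5, seed = 31)
  m <- train_model(f, model_config(lstm_hidden = 4, attention_key_dim = 5,
                                   max_epochs = 8, batch_size = 8, seed = 2))
  r <- recommend_dose(m, f, 2)
  expect_s3_class(r, "dose_recommendation")
  expect_equal(r$base_dose, unname(f$skip_raw[2, "interval_dose_mg"]))
  expect_equal(r$delta %% 250, 0)
  expect_lte(abs(r$delta), 1500)
  expect_gte(r$recommended_dose, 0)
  # the trace's zero-delta row equals the plain model prediction
  base_row <- r$trace[r$trace$delta == 0, ]
  expect_equal(base_row$predicted_trough, unname(predict_troughs(m, f)[2]),
               tolerance = 1e-10)
})

test_that("the reward curve bins distances and caps rewards at zero", {
  f <- random_features(30, 5, seed = 32)
  recs <- data.frame(base_dose = f$skip_raw[, "interval_dose_mg"],
                     recommended_dose = f$skip_raw[, "interval_dose_mg"])
  curve <- reward_curve(recs, f)
  expect_equal(curve$distance, 0)        # degenerate: all mass in bin 0
  expect_equal(curve$n, 30)
  expect_true(all(curve$mean_reward <= 0))

  recs2 <- recs
  recs2$recommended_dose <- recs$base_dose - rep(c(-500, 0, 500), 10)
  curve2 <- reward_curve(recs2, f)
  expect_setequal(curve2$distance, c(-500, 0, 500))
  expect_equal(sum(curve2$n), 30)
  expect_true(all(curve2$se >= 0))
})
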