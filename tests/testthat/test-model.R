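small_cfg <- function(...) {
  args <- utils::modifyList(
    list(lstm_hidden = 4, attention_heads = 2, attention_key_dim = 5,
         max_epochs = 40, batch_size = 8, l2_lambda = 1e-4,
         early_stop_patience = 40),
    list(...))
  do.call(model_config, args)
}

test_that("the parameter count matches the closed-form layer arithmetic", {
  cfg <- model_config()
  m <- build_model(10, 4, cfg)
  H <- cfg$lstm_hidden; dk <- cfg$attention_key_dim; nh <- cfg$attention_heads
  expected <- 4 * H * (10 + H + 1) +          # LSTM kernels + bias
    nh * 3 * (H * dk + dk) +                  # Q/K/V projections per head
    (nh * dk * H + H) +                       # output projection
    ((H + 4) + 1)                             # dense readout
  expect_equal(n_params(m), expected)
  expect_equal(n_params(m), 10341)
})

test_that("zeroing the skip weights makes the output skip-invariant", {
  cfg <- small_cfg()
  m <- build_model(6, 4, cfg)
  H <- cfg$lstm_hidden
  m$params$Wd[(H + 1):(H + 4), 1] <- 0
  f1 <- random_features(5, 6, seed = 1)
  f2 <- f1; f2$skip <- f2$skip + 10
  expect_equal(predict_troughs(m, f1), predict_troughs(m, f2))
})

test_that("permuting the time steps changes the prediction (order sensitivity)", {
  m <- build_model(6, 4, small_cfg())
  f <- random_features(3, 6, seed = 2)
  fp <- f; fp$X <- fp$X[, 24:1, , drop = FALSE]
  expect_false(isTRUE(all.equal(predict_troughs(m, f), predict_troughs(m, fp))))
})

test_that("backpropagated input gradients match finite differences", {
  ns <- asNamespace("troughcast")
  cfg <- small_cfg()
  m <- build_model(5, 4, cfg)
  withr::with_seed(9, {
    X <- array(rnorm(3 * 24 * 5), c(3, 24, 5))
    skip <- matrix(rnorm(12), 3, 4)
    y <- rnorm(3)
  })
  loss <- function(X, skip) {
    mean((ns$nn_forward(m$params, X, skip, cfg)$yhat - y)^2)
  }
  fwd <- ns$nn_forward(m$params, X, skip, cfg, keep_cache = TRUE)
  bwd <- ns$nn_backward(m$params, fwd$cache, 2 * (fwd$yhat - y) / 3, cfg)
  eps <- 1e-5
  idx <- withr::with_seed(4, sample(length(X), 25))
  for (i in idx) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    fd <- (loss(Xp, skip) - loss(Xm, skip)) / (2 * eps)
    expect_equal(bwd$dX[i], fd, tolerance = 1e-4)
  }
  for (i in seq_along(skip)) {
    sp <- skip; sp[i] <- sp[i] + eps
    sm <- skip; sm[i] <- sm[i] - eps
    fd <- (loss(X, sp) - loss(X, sm)) / (2 * eps)
    expect_equal(bwd$dskip[i], fd, tolerance = 1e-4)
  }
})

test_that("backpropagated parameter gradients match finite differences", {
  ns <- asNamespace("troughcast")
  cfg <- small_cfg()
  m <- build_model(5, 4, cfg)
  withr::with_seed(10, {
    X <- array(rnorm(2 * 24 * 5), c(2, 24, 5))
    skip <- matrix(rnorm(8), 2, 4)
    y <- rnorm(2)
  })
  loss_p <- function(p) mean((ns$nn_forward(p, X, skip, cfg)$yhat - y)^2)
  fwd <- ns$nn_forward(m$params, X, skip, cfg, keep_cache = TRUE)
  bwd <- ns$nn_backward(m$params, fwd$cache, 2 * (fwd$yhat - y) / 2, cfg)
  eps <- 1e-5
  for (nm in names(m$params)) {
    idx <- withr::with_seed(5, sample(length(m$params[[nm]]),
                                      min(4, length(m$params[[nm]]))))
    for (i in idx) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (loss_p(pp) - loss_p(pm)) / (2 * eps)
      expect_equal(bwd$grads[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training is deterministic and a learnable skip target is learned", {
  # trough is a noiseless linear function of the interval dose
  f <- random_features(60, 4, seed = 3,
                       y_fun = function(X, skip_raw) {
                         5 + 0.002 * skip_raw[, "interval_dose_mg"]
                       })
  cfg <- small_cfg(log_target = FALSE, learning_rate = 2e-2, seed = 21,
                   max_epochs = 120)
  m1 <- train_model(f, cfg)
  m2 <- train_model(f, cfg)
  expect_identical(m1$params, m2$params)
  pred <- predict_troughs(m1, f)
  expect_lt(mean(abs(pred - f$y)), 0.5)
})

test_that("very strong L2 shrinks predictions toward the target mean", {
  f <- random_features(40, 4, seed = 8)
  m <- train_model(f, small_cfg(l2_lambda = 50, max_epochs = 30, seed = 2))
  pred <- predict_troughs(m, f)
  expect_lt(stats::sd(pred), 0.25 * stats::sd(f$y) + 1e-6)
})

test_that("predictions are batch-invariant and order-preserving", {
  f <- random_features(7, 6, seed = 5)
  m <- build_model(6, 4, small_cfg())
  all_p <- predict_troughs(m, f)
  one <- f
  one$X <- f$X[3, , , drop = FALSE]; one$skip <- f$skip[3, , drop = FALSE]
  one$skip_raw <- f$skip_raw[3, , drop = FALSE]
  one$y <- f$y[3]; one$range <- f$range[3, , drop = FALSE]
  expect_equal(predict_troughs(m, one)[1], all_p[3])
  dup <- f
  dup$X <- f$X[c(2, 2), , , drop = FALSE]; dup$skip <- f$skip[c(2, 2), , drop = FALSE]
  p2 <- predict_troughs(m, dup)
  expect_equal(p2[1], p2[2])
})

test_that("save -> load -> predict round-trips exactly", {
  f <- random_features(10, 5, seed = 6)
  m <- train_model(f, small_cfg(max_epochs = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_troughs(m2, f), predict_troughs(m, f))
  expect_identical(m2$params, m$params)
})

test_that("relevance scores are gradient-times-input with zero-input nulling", {
  f <- random_features(12, 5, seed = 7)
  f$X[, , 2] <- 0   # a feature identically zero everywhere
  m <- train_model(f, small_cfg(max_epochs = 5, seed = 4))
  rel <- relevance_scores(m, f)
  expect_equal(max(abs(rel$sequence[, , 2])), 0)
  expect_equal(rel$table$score[rel$table$feature == "f2"], 0)
  expect_setequal(rel$table$feature,
                  c(f$schema$seq_cols, f$schema$skip_cols))
  expect_true(all(diff(rel$table$score) <= 1e-12))  # sorted decreasing
})

test_that("relevance gradients agree with finite differences of the prediction", {
  f <- random_features(2, 4, seed = 11)
  m <- train_model(f, small_cfg(max_epochs = 3, seed = 5))
  rel <- relevance_scores(m, f)
  eps <- 1e-5
  idx <- withr::with_seed(6, sample(length(f$X), 8))
  for (i in idx) {
    fp <- f; fp$X[i] <- fp$X[i] + eps
    fm <- f; fm$X[i] <- fm$X[i] - eps
    b <- arrayInd(i, dim(f$X))[1]  # sample owning this entry
    fd <- (predict_troughs(m, fp)[b] - predict_troughs(m, fm)[b]) / (2 * eps)
    grad <- rel$sequence[i] / ifelse(f$X[i] == 0, NA, f$X[i])
    expect_equal(grad, fd, tolerance = 1e-3)
  }
})

test_that("training aborts with a diagnostic on divergence", {
  f <- random_features(20, 4, seed = 9)
  cfg <- small_cfg(learning_rate = 1e155, log_target = FALSE, max_epochs = 5,
                   seed = 1)
  expect_error(train_model(f, cfg), "non-finite")
})
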