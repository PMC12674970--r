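#' Model architecture and training configuration
#'
#' Defaults mirror the reference architecture: an LSTM with 16 hidden units
#' over the 24-step prediction-day sequence, two attention heads of key
#' dimension 64 operating across the time axis, mean pooling over time, and a
#' single linear output unit that also receives the dose skip features
#' directly. Training minimizes mean squared error with Adam, weight decay on
#' all kernel matrices, plateau-based learning-rate halving, and early
#' stopping on a held-out slice of training encounters. The optimisation
#' defaults (learning rate, weight decay, batch size) come from a seeded
#' random search ([tune_model()]) on the synthetic task.
#'
#' @param lstm_hidden LSTM hidden-state size.
#' @param attention_heads Number of self-attention heads.
#' @param attention_key_dim Key/value dimension per head.
#' @param l2_lambda L2 penalty on the dense and recurrent kernels.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Training epoch cap.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param lr_plateau_patience Epochs without validation improvement before
#'   the learning rate is halved (down to `min_learning_rate`).
#' @param min_learning_rate Floor for the plateau-based learning-rate decay.
#' @param val_fraction Fraction of training encounters held out for early
#'   stopping.
#' @param pooling Temporal reduction applied to the attention outputs before
#'   the dense layer: `"mean"` (default), `"last"` (final time step), or
#'   `"max"` (per-unit maximum over time).
#' @param log_target Train on log-transformed troughs (predictions are mapped
#'   back to mg/L). Trough concentrations are strictly positive and
#'   multiplicative in dose and clearance, so the log scale is the natural
#'   regression scale; the loss is still mean squared error.
#' @param seed Seed for weight initialisation and data shuffling.
#' @return A list of class `model_config`.
#' @export
model_config <- function(lstm_hidden = 16, attention_heads = 2,
                         attention_key_dim = 64, l2_lambda = 0.1,
                         learning_rate = 5e-3, batch_size = 128,
                         max_epochs = 200, early_stop_patience = 30,
                         lr_plateau_patience = 8, min_learning_rate = 2e-4,
                         val_fraction = 0.15, log_target = TRUE,
                         pooling = c("mean", "last", "max"), seed = 1) {
  stopifnot(lstm_hidden >= 1, attention_heads >= 1, attention_key_dim >= 1,
            l2_lambda >= 0, learning_rate > 0, batch_size >= 1,
            max_epochs >= 1)
  structure(list(lstm_hidden = as.integer(lstm_hidden),
                 attention_heads = as.integer(attention_heads),
                 attention_key_dim = as.integer(attention_key_dim),
                 l2_lambda = l2_lambda, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_plateau_patience = as.integer(lr_plateau_patience),
                 min_learning_rate = min_learning_rate,
                 val_fraction = val_fraction, log_target = isTRUE(log_target),
                 pooling = match.arg(pooling), seed = as.integer(seed)),
            class = "model_config")
}

#' Build an untrained trough-regression model
#'
#' Initialises weights (Glorot uniform, forget-gate bias 1) for the given
#' feature schema. The computation graph is: 24-step sequence -> LSTM
#' returning all hidden states -> multi-head self-attention over the time
#' axis -> mean pooling -> concatenation with the dose skip vector -> one
#' linear output unit (mg/L on the standardized scale).
#'
#' @param n_seq Number of sequence features per time step.
#' @param n_skip Number of skip features.
#' @param config A [model_config()].
#' @param schema Optional feature schema (as produced by [build_features()])
#'   stored for input validation.
#' @return An object of class `trough_model`.
#' @export
build_model <- function(n_seq, n_skip, config = model_config(), schema = NULL) {
  if (!is.null(schema)) {
    if (length(schema$seq_cols) != n_seq || length(schema$skip_cols) != n_skip) {
      stop("feature schema is inconsistent with the requested dimensions")
    }
  }
  params <- with_seed(config$seed, init_params(n_seq, n_skip, config))
  structure(list(params = params, config = config, schema = schema,
                 stats = NULL, y_mean = 0, y_sd = 1, history = NULL),
            class = "trough_model")
}

#' Number of trainable parameters
#' @param model A `trough_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

check_schema <- function(model, features) {
  if (!is.null(model$schema) && !is.null(features$schema)) {
    if (!identical(model$schema$seq_cols, features$schema$seq_cols) ||
        !identical(model$schema$skip_cols, features$schema$skip_cols)) {
      stop("feature schema does not match the model's schema")
    }
  }
  if (dim(features$X)[3] != nrow(model$params$Wx)) {
    stop("sequence feature dimension does not match the model")
  }
}

batch_loss <- function(params, X, skip, y_std, config) {
  fwd <- nn_forward(params, X, skip, config, keep_cache = FALSE)
  mean((fwd$yhat - y_std)^2)
}

#' Train the trough regressor
#'
#' Minimizes mean squared error on standardized targets with Adam, L2
#' regularization on the dense and recurrent kernels, and early stopping on a
#' held-out fraction of training encounters (split at the encounter level).
#' Fully deterministic given `config$seed`.
#'
#' @param features A `trough_features` object from [build_features()]
#'   (training split).
#' @param config A [model_config()].
#' @param verbose Print per-epoch losses.
#' @return A trained `trough_model` carrying the weights, config, feature
#'   schema, normalization statistics, target scaling, and per-epoch history.
#' @export
train_model <- function(features, config = model_config(), verbose = FALSE) {
  stopifnot(inherits(features, "trough_features"))
  n <- length(features$y)
  if (n < 2) stop("need at least two training instances")
  model <- build_model(length(features$schema$seq_cols),
                       length(features$schema$skip_cols), config,
                       schema = features$schema)
  model$stats <- features$stats
  y_t <- if (config$log_target) log(pmax(features$y, 0.1)) else features$y
  model$y_mean <- mean(y_t)
  model$y_sd <- max(stats::sd(y_t), 1e-6)
  y_std <- (y_t - model$y_mean) / model$y_sd

  ids <- unique(features$meta$patient_id)
  n_val_enc <- max(1L, round(config$val_fraction * length(ids)))
  val_ids <- with_seed(config$seed + 1L,
                       sample(ids, min(n_val_enc, length(ids) - 1L)))
  val_idx <- which(features$meta$patient_id %in% val_ids)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0) tr_idx <- seq_len(n)
  if (length(val_idx) == 0) val_idx <- tr_idx

  Xv <- features$X[val_idx, , , drop = FALSE]
  sv <- features$skip[val_idx, , drop = FALSE]
  yv <- y_std[val_idx]

  params <- model$params
  state <- adam_init(params)
  lam <- config$l2_lambda
  lr <- config$learning_rate
  best <- list(loss = Inf, params = params, epoch = 0L)
  last_drop <- 0L
  swa <- NULL; swa_n <- 0L
  history <- list()
  order_seeds <- with_seed(config$seed + 2L,
                           sample.int(.Machine$integer.max %/% 2,
                                      config$max_epochs))
  for (epoch in seq_len(config$max_epochs)) {
    idx <- with_seed(order_seeds[epoch], sample(tr_idx))
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    tr_loss <- 0
    for (bt in batches) {
      Xb <- features$X[bt, , , drop = FALSE]
      sb <- features$skip[bt, , drop = FALSE]
      yb <- y_std[bt]
      fwd <- nn_forward(params, Xb, sb, config, keep_cache = TRUE)
      resid <- fwd$yhat - yb
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      }
      tr_loss <- tr_loss + loss * length(bt)
      bwd <- nn_backward(params, fwd$cache, 2 * resid / length(bt), config)
      g <- bwd$grads
      if (lam > 0) {
        # weight decay on every kernel (weight matrix); biases are exempt
        for (nm in names(params)) {
          if (is.matrix(params[[nm]])) g[[nm]] <- g[[nm]] + 2 * lam * params[[nm]]
        }
      }
      upd <- adam_step(params, g, state, lr)
      params <- upd$params
      state <- upd$state
    }
    val_loss <- batch_loss(params, Xv, sv, yv, config)
    history[[epoch]] <- data.frame(epoch = epoch,
                                   train_mse = tr_loss / length(tr_idx),
                                   val_mse = val_loss, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g", epoch,
                      tr_loss / length(tr_idx), val_loss, lr))
    }
    # running weight average over the epochs near the validation optimum
    # (stochastic weight averaging); kept if it validates better at the end
    if (is.finite(best$loss) && val_loss < 1.15 * best$loss) {
      swa_n <- swa_n + 1L
      swa <- if (is.null(swa)) params else
        mapply(function(a, b) a + (b - a) / swa_n, swa, params, SIMPLIFY = FALSE)
    }
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
    } else {
      # halve the learning rate on a validation plateau; stop when patience
      # is exhausted
      if (epoch - max(best$epoch, last_drop) >= config$lr_plateau_patience &&
          lr > config$min_learning_rate) {
        lr <- max(lr / 2, config$min_learning_rate)
        last_drop <- epoch
      }
      if (epoch - best$epoch >= config$early_stop_patience) break
    }
  }
  model$params <- best$params
  if (!is.null(swa) && swa_n >= 3) {
    swa_loss <- batch_loss(swa, Xv, sv, yv, config)
    if (swa_loss < best$loss) model$params <- swa
  }
  model$history <- do.call(rbind, history)
  model
}

#' Predict trough concentrations
#'
#' Runs the forward pass and de-standardizes the output to mg/L. Predictions
#' are deterministic, batch-order preserving, and independent across samples.
#' Negative raw outputs are clipped to 0 with the raw value kept in the
#' `"raw"` attribute.
#'
#' @param model A trained `trough_model`.
#' @param features A `trough_features` object built with the model's training
#'   statistics.
#' @return Numeric vector of predicted troughs (mg/L).
#' @export
predict_troughs <- function(model, features) {
  stopifnot(inherits(model, "trough_model"))
  check_schema(model, features)
  predict_arrays(model, features$X, features$skip)
}

# Shared prediction path for featurized arrays already on the model scale.
predict_arrays <- function(model, X, skip) {
  fwd <- nn_forward(model$params, X, skip, model$config)
  raw <- fwd$yhat * model$y_sd + model$y_mean
  out <- if (isTRUE(model$config$log_target)) exp(raw) else pmax(raw, 0)
  attr(out, "raw") <- raw
  out
}

#' Gradient-times-input relevance scores
#'
#' Attribution of each input feature to the predicted trough: the partial
#' derivative of the prediction (mg/L) with respect to the input, multiplied
#' by the input value. Per-feature aggregates are the mean absolute relevance
#' over time steps and samples; the ranked table separates continuous from
#' categorical (binary) features. A feature whose input is identically zero
#' has zero relevance by construction.
#'
#' @param model A trained `trough_model`.
#' @param features A `trough_features` object.
#' @return A list of class `relevance_scores`: `table` (ranked data frame
#'   with `feature`, `source` = sequence/skip, `class` =
#'   continuous/categorical, `score`), and the raw per-cell relevance arrays
#'   `sequence` (n x 24 x F) and `skip` (n x S).
#' @export
relevance_scores <- function(model, features) {
  stopifnot(inherits(model, "trough_model"))
  check_schema(model, features)
  fwd <- nn_forward(model$params, features$X, features$skip, model$config,
                    keep_cache = TRUE)
  # d(yhat_mgL)/d(input): samples are independent, so one pullback per sample
  # yields all per-sample input gradients in a single pass. Under log-target
  # training the chain rule contributes a factor of the prediction itself.
  raw <- fwd$yhat * model$y_sd + model$y_mean
  pull <- if (isTRUE(model$config$log_target)) exp(raw) * model$y_sd
          else rep(model$y_sd, length(raw))
  bwd <- nn_backward(model$params, fwd$cache, pull, model$config)
  rel_seq <- bwd$dX * features$X
  rel_skip <- bwd$dskip * features$skip
  seq_cols <- features$schema$seq_cols
  skip_cols <- features$schema$skip_cols
  seq_score <- apply(abs(rel_seq), 3, mean)
  skip_score <- colMeans(abs(rel_skip))
  tab <- data.frame(
    feature = c(seq_cols, skip_cols),
    source = c(rep("sequence", length(seq_cols)), rep("skip", length(skip_cols))),
    class = c(ifelse(seq_cols %in% features$schema$binary_cols,
                     "categorical", "continuous"),
              rep("continuous", length(skip_cols))),
    score = c(seq_score, skip_score),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$score), ]
  rownames(tab) <- NULL
  structure(list(table = tab, sequence = rel_seq, skip = rel_skip),
            class = "relevance_scores")
}

#' @export
print.relevance_scores <- function(x, n = 15, ...) {
  cat("Gradient-times-input relevance (top", n, "features)\n")
  print(utils::head(x$table, n))
  invisible(x)
}

#' @export
print.trough_model <- function(x, ...) {
  trained <- !is.null(x$history)
  cat(sprintf("Vancomycin trough sequence regressor (%s)\n",
              if (trained) "trained" else "untrained"))
  cat(sprintf("  LSTM %d | %d-head attention (key dim %d) | %s pooling | %d parameters\n",
              x$config$lstm_hidden, x$config$attention_heads,
              x$config$attention_key_dim, x$config$pooling %||% "mean",
              n_params(x)))
  if (trained) {
    cat(sprintf("  %d epochs, best validation MSE %.4f\n",
                nrow(x$history), min(x$history$val_mse)))
  }
  invisible(x)
}

#' Save / load a trained model
#'
#' The artifact is a single RDS file holding weights, configuration, feature
#' schema and normalization statistics; load -> predict round-trips exactly.
#'
#' @param model A `trough_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trough_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  structure(readRDS(path), class = "trough_model")
}

#' Seeded random search over training hyperparameters
#'
#' Draws `n_draws` configurations (log-uniform learning rate and L2, batch
#' size from `batch_choices`), trains each briefly, and returns the
#' configuration with the best validation loss together with the search
#' trace.
#'
#' @param features Training `trough_features`.
#' @param n_draws Number of random configurations.
#' @param max_epochs Epoch budget per draw.
#' @param lr_range,l2_range Log-uniform sampling bounds.
#' @param batch_choices Candidate batch sizes.
#' @param seed Seed for the draw sequence.
#' @return List with `best_config` and `trace` (data frame).
#' @export
tune_model <- function(features, n_draws = 8, max_epochs = 30,
                       lr_range = c(1e-3, 2e-2), l2_range = c(1e-6, 1e-3),
                       batch_choices = c(32, 64, 128), seed = 1) {
  draws <- with_seed(seed, data.frame(
    lr = exp(stats::runif(n_draws, log(lr_range[1]), log(lr_range[2]))),
    l2 = exp(stats::runif(n_draws, log(l2_range[1]), log(l2_range[2]))),
    batch = sample(batch_choices, n_draws, replace = TRUE)
  ))
  draws$val_mse <- NA_real_
  best <- NULL
  for (i in seq_len(n_draws)) {
    cfg <- model_config(learning_rate = draws$lr[i], l2_lambda = draws$l2[i],
                        batch_size = draws$batch[i], max_epochs = max_epochs,
                        seed = seed + i)
    fit <- train_model(features, cfg)
    draws$val_mse[i] <- min(fit$history$val_mse)
    if (is.null(best) || draws$val_mse[i] < best$val_mse) {
      best <- list(config = cfg, val_mse = draws$val_mse[i])
    }
  }
  list(best_config = best$config, trace = draws)
}
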