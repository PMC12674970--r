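# Sequence-regressor internals: parameter initialisation, forward pass,
# and backpropagation for the LSTM + multi-head self-attention + dose-skip
# architecture. Everything here works on standardized inputs/targets; the
# user-facing wrappers live in model.R.
#
# Conventions: batches of B samples; sequences of T = 24 steps; F sequence
# features; H LSTM units; S skip features; nh attention heads of key/value
# dimension dk. Stacked (B*T) x d matrices order rows time-fastest, so sample
# b occupies rows (b-1)*T + 1 ... b*T.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# Flat named list of parameter arrays. Gate order in the LSTM kernels is
# input, forget, cell, output; the forget-gate bias starts at 1.
init_params <- function(n_seq, n_skip, config) {
  H <- config$lstm_hidden
  dk <- config$attention_key_dim
  nh <- config$attention_heads
  p <- list(
    Wx = glorot(n_seq, 4 * H),
    Wh = glorot(H, 4 * H),
    b = c(rep(0, H), rep(1, H), rep(0, 2 * H))
  )
  for (h in seq_len(nh)) {
    p[[paste0("Wq", h)]] <- glorot(H, dk)
    p[[paste0("bq", h)]] <- rep(0, dk)
    p[[paste0("Wk", h)]] <- glorot(H, dk)
    p[[paste0("bk", h)]] <- rep(0, dk)
    p[[paste0("Wv", h)]] <- glorot(H, dk)
    p[[paste0("bv", h)]] <- rep(0, dk)
  }
  p$Wo <- glorot(nh * dk, H)
  p$bo <- rep(0, H)
  p$Wd <- glorot(H + n_skip, 1)
  p$bd <- 0
  p
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Forward pass. X: B x T x F array (standardized), skip: B x S matrix.
# Returns predictions (standardized scale) and, when keep_cache, everything
# backprop needs.
nn_forward <- function(params, X, skip, config, keep_cache = FALSE) {
  B <- dim(X)[1]; T_ <- dim(X)[2]
  H <- config$lstm_hidden
  dk <- config$attention_key_dim
  nh <- config$attention_heads

  h_prev <- matrix(0, B, H); c_prev <- matrix(0, B, H)
  lstm_cache <- if (keep_cache) vector("list", T_)
  Hmat <- matrix(0, B * T_, H)   # hidden states, time-fastest row order
  for (t in seq_len(T_)) {
    Xt <- matrix(X[, t, ], nrow = B)
    z <- Xt %*% params$Wx + h_prev %*% params$Wh
    z <- sweep(z, 2, params$b, "+")
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_t <- f * c_prev + i * g
    tc <- tanh(c_t)
    h_t <- o * tc
    if (keep_cache) {
      lstm_cache[[t]] <- list(Xt = Xt, h_prev = h_prev, c_prev = c_prev,
                              i = i, f = f, g = g, o = o, tc = tc)
    }
    Hmat[seq(t, by = T_, length.out = B), ] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }

  scale <- 1 / sqrt(dk)
  head_out <- vector("list", nh)
  attn_cache <- if (keep_cache) vector("list", nh)
  for (h in seq_len(nh)) {
    Q <- sweep(Hmat %*% params[[paste0("Wq", h)]], 2, params[[paste0("bq", h)]], "+")
    K <- sweep(Hmat %*% params[[paste0("Wk", h)]], 2, params[[paste0("bk", h)]], "+")
    V <- sweep(Hmat %*% params[[paste0("Wv", h)]], 2, params[[paste0("bv", h)]], "+")
    O <- matrix(0, B * T_, dk)
    A_list <- if (keep_cache) vector("list", B)
    for (b in seq_len(B)) {
      rb <- ((b - 1) * T_ + 1):(b * T_)
      A <- softmax_rows(Q[rb, , drop = FALSE] %*% t(K[rb, , drop = FALSE]) * scale)
      O[rb, ] <- A %*% V[rb, , drop = FALSE]
      if (keep_cache) A_list[[b]] <- A
    }
    head_out[[h]] <- O
    if (keep_cache) attn_cache[[h]] <- list(Q = Q, K = K, V = V, A = A_list)
  }
  Ocat <- do.call(cbind, head_out)
  attn <- sweep(Ocat %*% params$Wo, 2, params$bo, "+")
  arr <- array(attn, c(T_, B, H))
  pooling <- config$pooling %||% "mean"
  max_idx <- NULL
  pooled <- switch(pooling,
    mean = colMeans(arr),
    last = matrix(arr[T_, , ], B, H),
    max = {
      max_idx <- apply(arr, c(2, 3), which.max)
      apply(arr, c(2, 3), max)
    },
    stop("unknown pooling: ", pooling))
  if (B == 1) pooled <- matrix(pooled, 1, H)
  feat <- cbind(pooled, skip)
  yhat <- as.numeric(feat %*% params$Wd + params$bd)

  out <- list(yhat = yhat)
  if (keep_cache) {
    out$cache <- list(lstm = lstm_cache, attn = attn_cache, Hmat = Hmat,
                      Ocat = Ocat, feat = feat, B = B, T_ = T_,
                      max_idx = max_idx)
  }
  out
}

# Backward pass from d(loss)/d(yhat). Returns parameter gradients and
# gradients with respect to the inputs (dX: B x T x F, dskip: B x S).
nn_backward <- function(params, cache, dY, config) {
  B <- cache$B; T_ <- cache$T_
  H <- config$lstm_hidden
  dk <- config$attention_key_dim
  nh <- config$attention_heads
  scale <- 1 / sqrt(dk)
  dY <- matrix(dY, B, 1)

  grads <- list()
  grads$Wd <- crossprod(cache$feat, dY)
  grads$bd <- sum(dY)
  dfeat <- dY %*% t(params$Wd)
  dpooled <- dfeat[, 1:H, drop = FALSE]
  dskip <- dfeat[, (H + 1):ncol(dfeat), drop = FALSE]

  pooling <- config$pooling %||% "mean"
  if (pooling == "mean") {
    dattn <- dpooled[rep(seq_len(B), each = T_), , drop = FALSE] / T_
  } else if (pooling == "last") {
    dattn <- matrix(0, B * T_, H)
    dattn[seq(T_, by = T_, length.out = B), ] <- dpooled
  } else {
    dattn <- matrix(0, B * T_, H)
    rows <- (rep(seq_len(B), times = H) - 1) * T_ + as.vector(cache$max_idx)
    dattn[cbind(rows, rep(seq_len(H), each = B))] <- as.vector(dpooled)
  }
  grads$Wo <- crossprod(cache$Ocat, dattn)
  grads$bo <- colSums(dattn)
  dOcat <- dattn %*% t(params$Wo)

  dHmat <- matrix(0, B * T_, H)
  for (h in seq_len(nh)) {
    ac <- cache$attn[[h]]
    cols <- ((h - 1) * dk + 1):(h * dk)
    dO <- dOcat[, cols, drop = FALSE]
    dQ <- matrix(0, B * T_, dk); dK <- dQ; dV <- dQ
    for (b in seq_len(B)) {
      rb <- ((b - 1) * T_ + 1):(b * T_)
      A <- ac$A[[b]]
      dOb <- dO[rb, , drop = FALSE]
      dV[rb, ] <- crossprod(A, dOb)
      dA <- dOb %*% t(ac$V[rb, , drop = FALSE])
      dS <- A * (dA - rowSums(dA * A)) * scale
      dQ[rb, ] <- dS %*% ac$K[rb, , drop = FALSE]
      dK[rb, ] <- crossprod(dS, ac$Q[rb, , drop = FALSE])
    }
    grads[[paste0("Wq", h)]] <- crossprod(cache$Hmat, dQ)
    grads[[paste0("bq", h)]] <- colSums(dQ)
    grads[[paste0("Wk", h)]] <- crossprod(cache$Hmat, dK)
    grads[[paste0("bk", h)]] <- colSums(dK)
    grads[[paste0("Wv", h)]] <- crossprod(cache$Hmat, dV)
    grads[[paste0("bv", h)]] <- colSums(dV)
    dHmat <- dHmat + dQ %*% t(params[[paste0("Wq", h)]]) +
      dK %*% t(params[[paste0("Wk", h)]]) +
      dV %*% t(params[[paste0("Wv", h)]])
  }

  n_seq <- nrow(params$Wx)
  dX <- array(0, c(B, T_, n_seq))
  grads$Wx <- matrix(0, n_seq, 4 * H)
  grads$Wh <- matrix(0, H, 4 * H)
  grads$b <- rep(0, 4 * H)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    lc <- cache$lstm[[t]]
    dh <- matrix(dHmat[seq(t, by = T_, length.out = B), ], nrow = B) + dh_next
    do_ <- dh * lc$tc
    dc <- dc_next + dh * lc$o * (1 - lc$tc^2)
    di <- dc * lc$g
    dg <- dc * lc$i
    df <- dc * lc$c_prev
    dc_next <- dc * lc$f
    dz <- cbind(di * lc$i * (1 - lc$i),
                df * lc$f * (1 - lc$f),
                dg * (1 - lc$g^2),
                do_ * lc$o * (1 - lc$o))
    grads$Wx <- grads$Wx + crossprod(lc$Xt, dz)
    grads$Wh <- grads$Wh + crossprod(lc$h_prev, dz)
    grads$b <- grads$b + colSums(dz)
    dX[, t, ] <- dz %*% t(params$Wx)
    dh_next <- dz %*% t(params$Wh)
  }

  list(grads = grads, dX = dX, dskip = dskip)
}

# One Adam step over the flat parameter list; state carries first/second
# moments and the step counter.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0)
}
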