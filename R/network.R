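#' Tuned hyperparameters of the forecaster
#'
#' The four knobs searched by the swarm, each constrained to its search-space
#' bound: hidden units 16-64 (integer), dropout rate 0-0.4, learning rate
#' 1e-4 to 1e-2, batch size 16-64 (integer).
#'
#' @param hidden_units Integer in [16, 64].
#' @param dropout_rate Real in [0, 0.4].
#' @param learning_rate Real in [1e-4, 1e-2].
#' @param batch_size Integer in [16, 64].
#' @return A `hyperparams` list.
#' @export
hyperparams <- function(hidden_units = 40L, dropout_rate = 0.2,
                        learning_rate = 1e-3, batch_size = 32L) {
  hidden_units <- as.integer(hidden_units)
  batch_size <- as.integer(batch_size)
  if (hidden_units < 16L || hidden_units > 64L) {
    stop("hidden_units must be in [16, 64]", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate > 0.4) {
    stop("dropout_rate must be in [0, 0.4]", call. = FALSE)
  }
  if (learning_rate < 1e-4 || learning_rate > 1e-2) {
    stop("learning_rate must be in [1e-4, 1e-2]", call. = FALSE)
  }
  if (batch_size < 16L || batch_size > 64L) {
    stop("batch_size must be in [16, 64]", call. = FALSE)
  }
  structure(list(hidden_units = hidden_units, dropout_rate = dropout_rate,
                 learning_rate = learning_rate, batch_size = batch_size),
            class = "hyperparams")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize forecaster parameters
#'
#' Gate weights act on the concatenation `[h_prev, x_t]`; the attention score
#' dimension equals `hidden` (the smallest choice that adds no extra
#' hyperparameter); the head maps the context vector to all h x S outputs at
#' once. Weights are small scaled-uniform draws (seeded); biases start at
#' zero except the forget-gate bias, which starts at 1 so early training does
#' not erase the cell state.
#'
#' @param S Number of strata (input features per time step).
#' @param hidden Number of LSTM hidden units.
#' @param h Forecast horizon.
#' @param seed Integer seed.
#' @param zero If `TRUE`, all weights and biases are zero (useful for the
#'   closed-form micro-oracles).
#' @return A `model_params` list of weight matrices and bias vectors.
#' @export
init_model_params <- function(S, hidden, h, seed = 1L, zero = FALSE) {
  S <- as.integer(S); hidden <- as.integer(hidden); h <- as.integer(h)
  d <- hidden + S
  mk <- function(nr, nc, r) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  p <- withr::with_seed(as.integer(seed), {
    if (zero) {
      list(W_f = matrix(0, d, hidden), W_i = matrix(0, d, hidden),
           W_o = matrix(0, d, hidden), W_C = matrix(0, d, hidden),
           b_f = numeric(hidden), b_i = numeric(hidden),
           b_o = numeric(hidden), b_C = numeric(hidden),
           W_a = matrix(0, hidden, hidden), b_a = numeric(hidden),
           v = numeric(hidden),
           W_y = matrix(0, hidden, h * S), b_y = numeric(h * S))
    } else {
      rg <- 1 / sqrt(d); ra <- 1 / sqrt(hidden)
      list(W_f = mk(d, hidden, rg), W_i = mk(d, hidden, rg),
           W_o = mk(d, hidden, rg), W_C = mk(d, hidden, rg),
           b_f = rep(1, hidden), b_i = numeric(hidden),
           b_o = numeric(hidden), b_C = numeric(hidden),
           W_a = mk(hidden, hidden, ra), b_a = numeric(hidden),
           v = stats::runif(hidden, -ra, ra),
           W_y = mk(hidden, h * S, ra), b_y = numeric(h * S))
    }
  })
  p$S <- S; p$hidden <- hidden; p$h <- h
  class(p) <- "model_params"
  p
}

#' One LSTM cell update
#'
#' Computes the forget, input and output gates as sigmoids of affine maps of
#' the concatenation `[h_prev, x_t]`, the candidate as a tanh of the same
#' concatenation, then `C_t = f * C_prev + i * candidate` and
#' `h_t = o * tanh(C_t)`.
#'
#' @param x_t Length-S input vector (z-units).
#' @param h_prev,C_prev Length-`hidden` previous hidden and cell state.
#' @param params A `model_params`.
#' @return List with `h`, `C`, and the gate activations `f`, `i`, `o`.
#' @export
lstm_step <- function(x_t, h_prev, C_prev, params) {
  if (length(x_t) != params$S || length(h_prev) != params$hidden ||
      length(C_prev) != params$hidden) {
    stop("lstm_step: shape mismatch with params", call. = FALSE)
  }
  z <- c(h_prev, x_t)
  f <- sigmoid(drop(z %*% params$W_f) + params$b_f)
  i <- sigmoid(drop(z %*% params$W_i) + params$b_i)
  o <- sigmoid(drop(z %*% params$W_o) + params$b_o)
  g <- tanh(drop(z %*% params$W_C) + params$b_C)
  C_t <- f * C_prev + i * g
  h_t <- o * tanh(C_t)
  list(h = h_t, C = C_t, f = f, i = i, o = o)
}

#' Additive attention weights over encoder states
#'
#' Scores each per-step hidden state with `e_t = v' tanh(W_a h_t + b_a)` and
#' softmax-normalizes the scores into a probability vector over the w steps.
#'
#' @param H w x hidden matrix of hidden states (row t = step t).
#' @param params A `model_params`.
#' @return Length-w weight vector; positive, summing to 1.
#' @export
attention_weights <- function(H, params) {
  H <- rbind(H)
  if (ncol(H) != params$hidden) stop("attention_weights: H has wrong width", call. = FALSE)
  e <- drop(tanh(sweep(H %*% params$W_a, 2L, params$b_a, "+")) %*% params$v)
  e <- e - max(e)                       # stabilized softmax
  w <- exp(e)
  w / sum(w)
}

#' Attention context vector
#'
#' @param H w x hidden matrix of hidden states.
#' @param alpha Length-w weights summing to 1.
#' @return Length-`hidden` convex combination of the rows of `H`.
#' @export
attention_context <- function(H, alpha) {
  H <- rbind(H)
  if (length(alpha) != nrow(H)) stop("attention_context: length mismatch", call. = FALSE)
  drop(crossprod(H, alpha))
}

#' Single-shot multi-horizon output head
#'
#' One affine map from the context vector to all h x S forecasts at once
#' (no recursion across horizons). The length h*S output vector is reshaped
#' column-major: entry (k, s) of the result is horizon step k of stratum s.
#'
#' @param a Length-`hidden` context vector.
#' @param params A `model_params`.
#' @return h x S matrix of forecasts in z-units.
#' @export
output_head <- function(a, params) {
  if (length(a) != params$hidden) stop("output_head: context has wrong length", call. = FALSE)
  y <- drop(a %*% params$W_y) + params$b_y
  matrix(y, params$h, params$S)
}

#' Forward pass of the forecaster
#'
#' Runs the LSTM over the w window steps from zero initial state, pools the
#' per-step hidden states with additive attention (or takes the last hidden
#' state when `attention = FALSE`), and applies the output head. Inference
#' (`training = FALSE`, the default) is a pure deterministic function of the
#' window and parameters; with `training = TRUE` an inverted-dropout mask at
#' rate `dropout_rate` is applied to the hidden states before pooling.
#'
#' @param window w x S matrix in z-units.
#' @param params A `model_params`.
#' @param training Apply dropout? Default `FALSE`.
#' @param dropout_rate Dropout rate used when `training = TRUE`.
#' @param attention Use the attention pooling (default) or the last hidden
#'   state.
#' @return h x S forecast matrix in z-units.
#' @export
forward <- function(window, params, training = FALSE, dropout_rate = 0,
                    attention = TRUE) {
  window <- rbind(window)
  if (ncol(window) != params$S) stop("forward: window has wrong width", call. = FALSE)
  w <- nrow(window)
  H <- matrix(0, w, params$hidden)
  h_t <- numeric(params$hidden); C_t <- numeric(params$hidden)
  for (t in seq_len(w)) {
    st <- lstm_step(window[t, ], h_t, C_t, params)
    h_t <- st$h; C_t <- st$C
    H[t, ] <- h_t
  }
  if (training && dropout_rate > 0) {
    keep <- matrix(stats::runif(length(H)) >= dropout_rate, nrow(H), ncol(H))
    H <- H * keep / (1 - dropout_rate)
  }
  a <- if (attention) attention_context(H, attention_weights(H, params)) else H[w, ]
  output_head(a, params)
}

# ---- batched forward/backward used by the trainer --------------------------
#
# X: N x w x S array, Y: N x (h*S) matrix (column-major flatten as in
# output_head). Returns predictions and, when Y is supplied, the full
# gradient list (same names as params) of
#   L = mean((yhat - Y)^2) + l2 * sum(W^2 over weight matrices)
# derived by backpropagation through time.

forward_backward <- function(X, params, Y = NULL, dropout_mask = NULL,
                             attention = TRUE, l2 = 0) {
  n <- dim(X)[1L]; w <- dim(X)[2L]; S <- dim(X)[3L]; hd <- params$hidden
  Hs <- vector("list", w)   # hidden states per step (n x hd)
  Cs <- vector("list", w)   # cell states
  Fs <- Is <- Os <- Gs <- vector("list", w)
  h_t <- matrix(0, n, hd); C_t <- matrix(0, n, hd)
  for (t in seq_len(w)) {
    Z <- cbind(h_t, matrix(X[, t, , drop = FALSE], n, S))
    f <- sigmoid(sweep(Z %*% params$W_f, 2L, params$b_f, "+"))
    i <- sigmoid(sweep(Z %*% params$W_i, 2L, params$b_i, "+"))
    o <- sigmoid(sweep(Z %*% params$W_o, 2L, params$b_o, "+"))
    g <- tanh(sweep(Z %*% params$W_C, 2L, params$b_C, "+"))
    C_t <- f * C_t + i * g
    h_t <- o * tanh(C_t)
    Fs[[t]] <- f; Is[[t]] <- i; Os[[t]] <- o; Gs[[t]] <- g
    Cs[[t]] <- C_t; Hs[[t]] <- h_t
  }
  # dropout on pooled hidden states (training only)
  Hd <- Hs
  if (!is.null(dropout_mask)) {
    for (t in seq_len(w)) Hd[[t]] <- Hs[[t]] * dropout_mask[[t]]
  }
  if (attention) {
    U <- vector("list", w)          # tanh(W_a h + b_a), n x hd
    E <- matrix(0, n, w)            # scores
    for (t in seq_len(w)) {
      U[[t]] <- tanh(sweep(Hd[[t]] %*% params$W_a, 2L, params$b_a, "+"))
      E[, t] <- U[[t]] %*% params$v
    }
    E <- E - apply(E, 1L, max)
    A <- exp(E); A <- A / rowSums(A)   # n x w attention weights
    ctx <- matrix(0, n, hd)
    for (t in seq_len(w)) ctx <- ctx + A[, t] * Hd[[t]]
  } else {
    ctx <- Hd[[w]]
  }
  yhat <- sweep(ctx %*% params$W_y, 2L, params$b_y, "+")
  if (is.null(Y)) return(list(pred = yhat))

  mse <- mean((yhat - Y)^2)
  # attention parameters are inert (and unpenalized) when attention is off
  wt_names <- c("W_f", "W_i", "W_o", "W_C", "W_y", if (attention) "W_a")
  sq <- sum(vapply(wt_names, function(nm) sum(params[[nm]]^2), 0))
  if (attention) sq <- sq + sum(params$v^2)
  l2pen <- if (l2 > 0) l2 * sq else 0
  loss <- mse + l2pen

  gr <- list()
  dY <- 2 * (yhat - Y) / length(Y)
  gr$W_y <- crossprod(ctx, dY) + if (l2 > 0) 2 * l2 * params$W_y else 0
  gr$b_y <- colSums(dY)
  dctx <- dY %*% t(params$W_y)
  dH <- vector("list", w)           # gradients w.r.t. (dropped-out) H
  if (attention) {
    dA <- matrix(0, n, w)
    for (t in seq_len(w)) {
      dH[[t]] <- A[, t] * dctx
      dA[, t] <- rowSums(dctx * Hd[[t]])
    }
    dE <- A * (dA - rowSums(A * dA))  # softmax backward, row-wise
    gr$W_a <- matrix(0, hd, hd); gr$b_a <- numeric(hd); gr$v <- numeric(hd)
    for (t in seq_len(w)) {
      gr$v <- gr$v + drop(crossprod(U[[t]], dE[, t]))
      dU <- outer(dE[, t], params$v)           # n x hd
      dZa <- dU * (1 - U[[t]]^2)
      gr$W_a <- gr$W_a + crossprod(Hd[[t]], dZa)
      gr$b_a <- gr$b_a + colSums(dZa)
      dH[[t]] <- dH[[t]] + dZa %*% t(params$W_a)
    }
    gr$W_a <- gr$W_a + 2 * l2 * params$W_a
    gr$v <- gr$v + 2 * l2 * params$v
  } else {
    for (t in seq_len(w)) dH[[t]] <- matrix(0, n, hd)
    dH[[w]] <- dctx
    gr$W_a <- matrix(0, hd, hd); gr$b_a <- numeric(hd); gr$v <- numeric(hd)
  }
  # undo dropout scaling into the raw hidden states
  if (!is.null(dropout_mask)) {
    for (t in seq_len(w)) dH[[t]] <- dH[[t]] * dropout_mask[[t]]
  }
  # backprop through time
  for (nm in c("W_f", "W_i", "W_o", "W_C")) gr[[nm]] <- matrix(0, hd + S, hd)
  for (nm in c("b_f", "b_i", "b_o", "b_C")) gr[[nm]] <- numeric(hd)
  dh_next <- matrix(0, n, hd); dC_next <- matrix(0, n, hd)
  for (t in rev(seq_len(w))) {
    dh <- dH[[t]] + dh_next
    C_t <- Cs[[t]]; tC <- tanh(C_t)
    f <- Fs[[t]]; i <- Is[[t]]; o <- Os[[t]]; g <- Gs[[t]]
    dC <- dC_next + dh * o * (1 - tC^2)
    C_prev <- if (t > 1L) Cs[[t - 1L]] else matrix(0, n, hd)
    h_prev <- if (t > 1L) Hs[[t - 1L]] else matrix(0, n, hd)
    do_ <- dh * tC
    df <- dC * C_prev
    di <- dC * g
    dg <- dC * i
    dzf <- df * f * (1 - f)
    dzi <- di * i * (1 - i)
    dzo <- do_ * o * (1 - o)
    dzg <- dg * (1 - g^2)
    Z <- cbind(h_prev, matrix(X[, t, , drop = FALSE], n, S))
    gr$W_f <- gr$W_f + crossprod(Z, dzf); gr$b_f <- gr$b_f + colSums(dzf)
    gr$W_i <- gr$W_i + crossprod(Z, dzi); gr$b_i <- gr$b_i + colSums(dzi)
    gr$W_o <- gr$W_o + crossprod(Z, dzo); gr$b_o <- gr$b_o + colSums(dzo)
    gr$W_C <- gr$W_C + crossprod(Z, dzg); gr$b_C <- gr$b_C + colSums(dzg)
    dZ <- dzf %*% t(params$W_f) + dzi %*% t(params$W_i) +
      dzo %*% t(params$W_o) + dzg %*% t(params$W_C)
    dh_next <- dZ[, seq_len(hd), drop = FALSE]
    dC_next <- dC * f
  }
  if (l2 > 0) {
    for (nm in c("W_f", "W_i", "W_o", "W_C")) {
      gr[[nm]] <- gr[[nm]] + 2 * l2 * params[[nm]]
    }
  }
  list(pred = yhat, loss = loss, mse = mse, grads = gr)
}

# Batched predictions (z-units), N x (h*S)
predict_batch <- function(X, params, attention = TRUE) {
  forward_backward(X, params, Y = NULL, attention = attention)$pred
}

# Flatten an N x h x S target array to the N x (h*S) column-major layout used
# by the head.
flatten_targets <- function(targets) {
  n <- dim(targets)[1L]
  matrix(targets, n, dim(targets)[2L] * dim(targets)[3L])
}
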