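# Independent oracles used by the unit and acceptance tests. These are
# deliberately written as plain scalar-loop transcriptions, sharing no code
# path with the package's vectorized implementations.

# ---- metric oracles (loop transcriptions) ----------------------------------
oracle_mse <- function(y, p) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - p[i])^2
  s / length(y)
}
oracle_mae <- function(y, p) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - p[i])
  s / length(y)
}
oracle_mape <- function(y, p) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs((y[i] - p[i]) / y[i])
  s / length(y) * 100
}
oracle_r2 <- function(y, p) {
  yb <- sum(y) / length(y)
  ssr <- 0; sst <- 0
  for (i in seq_along(y)) {
    ssr <- ssr + (y[i] - p[i])^2
    sst <- sst + (y[i] - yb)^2
  }
  1 - ssr / sst
}
oracle_nrmse <- function(y, p) {
  sqrt(oracle_mse(y, p)) / (max(y) - min(y))
}

# ---- recurrent-network oracle ----------------------------------------------
# Straight per-unit transcription of the gate equations, the additive
# attention, and the affine head.
oracle_lstm_cell <- function(x_t, h_prev, C_prev, pr) {
  hd <- pr$hidden
  z <- c(h_prev, x_t)
  gate <- function(W, b) {
    out <- numeric(hd)
    for (j in seq_len(hd)) {
      acc <- b[j]
      for (k in seq_along(z)) acc <- acc + z[k] * W[k, j]
      out[j] <- 1 / (1 + exp(-acc))
    }
    out
  }
  cand <- numeric(hd)
  for (j in seq_len(hd)) {
    acc <- pr$b_C[j]
    for (k in seq_along(z)) acc <- acc + z[k] * pr$W_C[k, j]
    cand[j] <- tanh(acc)
  }
  f <- gate(pr$W_f, pr$b_f); i <- gate(pr$W_i, pr$b_i); o <- gate(pr$W_o, pr$b_o)
  C_t <- f * C_prev + i * cand
  list(h = o * tanh(C_t), C = C_t)
}

oracle_attention <- function(H, pr) {
  w <- nrow(H); hd <- pr$hidden
  e <- numeric(w)
  for (t in seq_len(w)) {
    acc <- 0
    for (j in seq_len(hd)) {
      z <- pr$b_a[j]
      for (k in seq_len(hd)) z <- z + pr$W_a[k, j] * H[t, k]
      acc <- acc + pr$v[j] * tanh(z)
    }
    e[t] <- acc
  }
  ex <- exp(e - max(e))
  ex / sum(ex)
}

oracle_forward <- function(window, pr) {
  w <- nrow(window); hd <- pr$hidden
  H <- matrix(0, w, hd)
  h_t <- numeric(hd); C_t <- numeric(hd)
  for (t in seq_len(w)) {
    st <- oracle_lstm_cell(window[t, ], h_t, C_t, pr)
    h_t <- st$h; C_t <- st$C
    H[t, ] <- h_t
  }
  alpha <- oracle_attention(H, pr)
  a <- numeric(hd)
  for (t in seq_len(w)) a <- a + alpha[t] * H[t, ]
  y <- numeric(pr$h * pr$S)
  for (j in seq_along(y)) {
    acc <- pr$b_y[j]
    for (k in seq_len(hd)) acc <- acc + a[k] * pr$W_y[k, j]
    y[j] <- acc
  }
  matrix(y, pr$h, pr$S)
}

# ---- fixtures ---------------------------------------------------------------
# Small deterministic panel: linear-plus-curvature series per stratum, all
# positive, non-constant.
tiny_panel <- function(T_years = 20L, S = 3L, start_year = 2000L) {
  years <- start_year + seq_len(T_years) - 1L
  strata <- data.frame(
    sex = rep(c("male", "female"), length.out = S),
    age_group = paste0("g", seq_len(S)),
    stringsAsFactors = FALSE
  )
  vals <- sapply(seq_len(S), function(s) {
    10 * s + seq_len(T_years) * (0.5 + 0.1 * s) + 0.02 * s * seq_len(T_years)^2
  })
  asir_panel(years, strata, vals)
}

# Tiny windowed datasets for trainer tests
tiny_windows <- function(n = 8L, w = 4L, S = 2L, h = 2L, seed = 1L,
                         targets = NULL) {
  withr::with_seed(seed, {
    inputs <- array(stats::rnorm(n * w * S), c(n, w, S))
    if (is.null(targets)) targets <- array(stats::rnorm(n * h * S), c(n, h, S))
    structure(list(inputs = inputs, targets = targets,
                   anchor_years = seq_len(n), w = w, h = h,
                   strata = data.frame(sex = rep("male", S),
                                       age_group = paste0("g", seq_len(S)))),
              class = "windowed_dataset")
  })
}
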