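zero_params <- function(S = 3L, hidden = 4L, h = 2L) {
  init_model_params(S, hidden, h, zero = TRUE)
}

test_that("zero-weight cell gives gates 0.5 and halves the carried state", {
  pr <- zero_params()
  C0 <- c(0.4, -1, 2, 0)
  st <- lstm_step(c(1, -2, 3), numeric(4), C0, pr)
  expect_equal(st$f, rep(0.5, 4))
  expect_equal(st$i, rep(0.5, 4))
  expect_equal(st$o, rep(0.5, 4))
  expect_equal(st$C, 0.5 * C0)
  expect_equal(st$h, 0.5 * tanh(0.5 * C0))
})

test_that("a saturated forget gate preserves the cell state", {
  pr <- zero_params()
  pr$b_f <- rep(20, 4)
  C0 <- c(1, -0.5, 0.25, 3)
  st <- lstm_step(c(0.1, 0.2, 0.3), numeric(4), C0, pr)
  expect_equal(st$C, C0, tolerance = 1e-8)
})

test_that("gate outputs stay in (0,1) and the cell grows at most linearly", {
  pr <- init_model_params(3L, 4L, 2L, seed = 8)
  h_t <- numeric(4); C_t <- numeric(4)
  withr::with_seed(3, {
    for (t in 1:20) {
      st <- lstm_step(runif(3, -1, 1), h_t, C_t, pr)
      expect_true(all(st$f > 0 & st$f < 1))
      expect_true(all(st$i > 0 & st$i < 1))
      expect_true(all(st$o > 0 & st$o < 1))
      expect_true(all(abs(st$h) < 1))
      expect_true(all(abs(st$C) <= t + 1e-12))   # |C_t| <= |C_0| + t
      h_t <- st$h; C_t <- st$C
    }
  })
})

test_that("cell update matches the scalar-loop transcription oracle", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      pr <- init_model_params(4L, 6L, 2L, seed = rep)
      x <- rnorm(4); h0 <- rnorm(6) * 0.3; C0 <- rnorm(6)
      got <- lstm_step(x, h0, C0, pr)
      want <- oracle_lstm_cell(x, h0, C0, pr)
      expect_equal(got$h, want$h, tolerance = 1e-10)
      expect_equal(got$C, want$C, tolerance = 1e-10)
    }
  })
})

test_that("attention weights form a probability vector with the right limits", {
  pr <- init_model_params(3L, 5L, 2L, seed = 4)
  # identical hidden states -> uniform weights
  H <- matrix(rep(rnorm(5), each = 6), 6, 5)
  expect_equal(attention_weights(H, pr), rep(1 / 6, 6))
  # one score larger by ~100 -> weight saturates near 1
  pr2 <- zero_params(3L, 2L, 2L)
  pr2$v <- c(100, 0)                   # e_t = 100 * tanh(50 * h_t1)
  pr2$W_a <- diag(2) * 50
  H2 <- matrix(0, 4, 2)
  H2[3L, ] <- c(1, 0)
  a2 <- attention_weights(H2, pr2)
  expect_gt(a2[3L], 0.999)
  # random case vs oracle; weights always positive, summing to 1
  withr::with_seed(12, {
    for (rep in 1:5) {
      H3 <- matrix(rnorm(8 * 5), 8, 5)
      a3 <- attention_weights(H3, pr)
      expect_equal(sum(a3), 1, tolerance = 1e-12)
      expect_true(all(a3 > 0))
      expect_equal(a3, oracle_attention(H3, pr), tolerance = 1e-12)
    }
  })
})

test_that("attention context is the weighted row combination", {
  H <- matrix(1:12, 4, 3)
  expect_equal(attention_context(H, c(0, 0, 1, 0)), H[3L, ])
  expect_equal(attention_context(H, rep(0.25, 4)), colMeans(H))
  withr::with_seed(13, {
    H2 <- matrix(rnorm(20), 5, 4)
    al <- runif(5); al <- al / sum(al)
    expect_equal(attention_context(H2, al), drop(al %*% H2), tolerance = 1e-12)
  })
})

test_that("output head is affine with the declared 24 x 5 = 120 output block", {
  pr <- init_model_params(24L, 32L, 5L, seed = 6)
  a <- rnorm(32)
  y <- output_head(a, pr)
  expect_equal(dim(y), c(5L, 24L))
  expect_equal(length(y), 120L)
  # zero weights return the bias
  pr0 <- init_model_params(24L, 32L, 5L, zero = TRUE)
  pr0$b_y <- seq_len(120) / 10
  expect_equal(output_head(rnorm(32), pr0), matrix(pr0$b_y, 5, 24))
  # linearity: additivity and homogeneity against direct matrix algebra
  a1 <- rnorm(32); a2 <- rnorm(32)
  expect_equal(output_head(a1 + a2, pr) - output_head(numeric(32), pr),
               (output_head(a1, pr) - output_head(numeric(32), pr)) +
                 (output_head(a2, pr) - output_head(numeric(32), pr)),
               tolerance = 1e-10)
  expect_equal(output_head(2 * a1, pr),
               matrix(drop((2 * a1) %*% pr$W_y) + pr$b_y, 5, 24),
               tolerance = 1e-12)
})

test_that("forward composes the stages and is deterministic at inference", {
  pr <- init_model_params(4L, 6L, 3L, seed = 21)
  withr::with_seed(22, {
    win <- matrix(rnorm(5 * 4), 5, 4)
  })
  y1 <- forward(win, pr)
  y2 <- forward(win, pr)
  expect_identical(y1, y2)
  expect_equal(y1, oracle_forward(win, pr), tolerance = 1e-8)
  # all-zero parameters forecast the (reshaped) bias for any window
  pr0 <- init_model_params(4L, 6L, 3L, zero = TRUE)
  pr0$b_y <- rnorm(12)
  expect_equal(forward(win, pr0), matrix(pr0$b_y, 3, 4))
  expect_equal(forward(win * 5 - 2, pr0), matrix(pr0$b_y, 3, 4))
})

test_that("batched forward agrees with the per-sample path", {
  pr <- init_model_params(3L, 5L, 2L, seed = 31)
  withr::with_seed(32, {
    X <- array(rnorm(7 * 6 * 3), c(7, 6, 3))
  })
  batch <- asircast:::predict_batch(X, pr)
  for (k in c(1L, 4L, 7L)) {
    expect_equal(matrix(batch[k, ], 2, 3), forward(X[k, , ], pr),
                 tolerance = 1e-12)
  }
  # no-attention pooling: last hidden state
  batch2 <- asircast:::predict_batch(X, pr, attention = FALSE)
  expect_equal(matrix(batch2[2L, ], 2, 3),
               forward(X[2L, , ], pr, attention = FALSE), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  pr <- init_model_params(3L, 4L, 2L, seed = 41)
  withr::with_seed(42, {
    X <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
    Y <- matrix(rnorm(5 * 6), 5, 6)      # h * S = 2 * 3
  })
  for (att in c(TRUE, FALSE)) {
    fb <- asircast:::forward_backward(X, pr, Y, attention = att, l2 = 1e-3)
    loss_at <- function(p) asircast:::forward_backward(X, p, Y, attention = att,
                                                       l2 = 1e-3)$loss
    withr::with_seed(43, {
      for (nm in c("W_f", "W_i", "W_o", "W_C", "b_f", "W_a", "v", "W_y", "b_y")) {
        idx <- sample.int(length(pr[[nm]]), 1L)
        eps <- 1e-6
        p1 <- pr; p1[[nm]][idx] <- p1[[nm]][idx] + eps
        p2 <- pr; p2[[nm]][idx] <- p2[[nm]][idx] - eps
        numg <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
        expect_equal(fb$grads[[nm]][idx], numg, tolerance = 1e-5)
      }
    })
  }
})

test_that("shape mismatches are rejected", {
  pr <- zero_params()
  expect_error(lstm_step(c(1, 2), numeric(4), numeric(4), pr), "shape")
  expect_error(attention_weights(matrix(0, 3, 7), pr), "width")
  expect_error(output_head(numeric(7), pr), "length")
  expect_error(forward(matrix(0, 5, 9), pr), "width")
})
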