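unit_space <- function(ndim = 1L, lo = -5, hi = 5) {
  search_space(lapply(seq_len(ndim), function(j) {
    list(name = paste0("x", j), lower = lo, upper = hi,
         scale = "linear", kind = "real")
  }))
}

test_that("inertia schedule hits 0.9, 0.7, 0.5 and decreases monotonically", {
  expect_equal(inertia_at(0, 50), 0.9)
  expect_equal(inertia_at(25, 50), 0.7)
  expect_equal(inertia_at(50, 50), 0.5)
  om <- vapply(0:50, inertia_at, 0, max_iter = 50)
  expect_true(all(diff(om) < 0))
  expect_error(inertia_at(51, 50))
})

test_that("decode_position applies log, rounding and clipping rules", {
  hp <- decode_position(c(40.0, 0.2, -3.0, 32.0))
  expect_s3_class(hp, "hyperparams")
  expect_equal(hp$hidden_units, 40L)
  expect_equal(hp$dropout_rate, 0.2)
  expect_equal(hp$learning_rate, 1e-3, tolerance = 1e-12)
  expect_equal(hp$batch_size, 32L)
  expect_equal(decode_position(c(40.6, 0.2, -3, 32))$hidden_units, 41L)
  expect_equal(decode_position(c(40, 0.2, -4, 32))$learning_rate, 1e-4,
               tolerance = 1e-12)
  expect_equal(decode_position(c(16.4, 0, -2, 63.7))$batch_size, 64L)
})

test_that("degenerate coefficients give ballistic motion and fixed points", {
  sp <- unit_space(1L)
  st <- withr::with_seed(1, asircast:::init_swarm(sp, 2L))
  st$position[, 1] <- c(1, -2)
  st$velocity[, 1] <- c(0.5, 0.25)
  st2 <- pso_step(st, function(x) sum(x^2), omega = 1, c1 = 0, c2 = 0)
  expect_equal(st2$position[, 1], c(1.5, -1.75))
  expect_equal(st2$velocity[, 1], c(0.5, 0.25))

  # single particle at its own (personal = global) best with zero velocity
  st3 <- withr::with_seed(2, asircast:::init_swarm(sp, 1L))
  st3$position[1, ] <- 0.3
  st3$velocity[1, ] <- 0
  for (omega in c(0.9, 0.5)) {
    st4 <- pso_step(st3, function(x) sum(x^2), omega = omega)
    expect_equal(st4$position[1, ], 0.3)
  }
})

test_that("the velocity update matches a pencil-and-paper evaluation", {
  # 2 particles, 1-D, injected r1 = r2 = 0.5; f(x) = x^2
  sp <- unit_space(1L)
  st <- withr::with_seed(3, asircast:::init_swarm(sp, 2L))
  st$position[, 1] <- c(2, -1)
  st$velocity[, 1] <- c(1, -0.5)
  st$pbest_pos[, 1] <- c(2, -1)
  half <- function(n) rep(0.5, n)
  st2 <- pso_step(st, function(x) x^2, omega = 0.8, c1 = 2, c2 = 2,
                  rand_fn = half)
  # after evaluation: pbest_1 = 4 at 2, pbest_2 = 1 at -1, gbest = -1
  expect_equal(st2$gbest_score, 1)
  # v1 = 0.8*1 + 2*0.5*(2-2) + 2*0.5*(-1-2) = 0.8 - 3 = -2.2; x1 = -0.2
  # v2 = 0.8*(-0.5) + 0 + 0 = -0.4; x2 = -1.4
  expect_equal(st2$velocity[, 1], c(-2.2, -0.4))
  expect_equal(st2$position[, 1], c(-0.2, -1.4))
})

test_that("failing fitness scores a particle +Inf instead of aborting", {
  sp <- unit_space(1L)
  st <- withr::with_seed(4, asircast:::init_swarm(sp, 2L))
  bad <- function(x) if (x[1] > st$position[1, 1] - 1e-9 &&
                           x[1] < st$position[1, 1] + 1e-9) stop("boom") else sum(x^2)
  expect_warning(st2 <- pso_step(st, bad, omega = 0.9), "fitness")
  expect_identical(st2$pbest_score[1L], Inf)
  expect_true(is.finite(st2$gbest_score))
})

test_that("sphere minimum is recovered under the production swarm settings", {
  sp <- unit_space(3L)
  best <- vapply(1:10, function(s) {
    pso_optimize(function(x) sum(x^2), sp, n_particles = 10L, max_iter = 50L,
                 patience = 50L, seed = s)$best_score
  }, 0)
  expect_lt(median(best), 1e-3)
})

test_that("a quadratic with its argmin outside the box ends at the bound", {
  sp <- unit_space(1L, lo = -5, hi = 5)
  res <- pso_optimize(function(x) (x[1] - 9)^2, sp, n_particles = 10L,
                      max_iter = 50L, patience = 50L, seed = 1)
  expect_equal(res$best_position, 5, tolerance = 1e-9)
})

test_that("the best-score trace is monotone and seeded runs are identical", {
  sp <- unit_space(2L)
  withr::with_seed(9, {
    wobbly <- function(x) sum(sin(3 * x) + 0.3 * x^2)
    r1 <- pso_optimize(wobbly, sp, n_particles = 6L, max_iter = 30L, seed = 5)
    r2 <- pso_optimize(wobbly, sp, n_particles = 6L, max_iter = 30L, seed = 5)
    r3 <- pso_optimize(wobbly, sp, n_particles = 6L, max_iter = 30L, seed = 6)
  })
  expect_true(all(diff(r1$trace$best_score) <= 0))
  expect_identical(r1$trace, r2$trace)
  expect_false(identical(r1$trace, r3$trace))
})

test_that("constant fitness stalls out after patience + 1 sweeps", {
  sp <- unit_space(2L)
  res <- pso_optimize(function(x) 1, sp, n_particles = 4L, max_iter = 50L,
                      patience = 5L, seed = 2)
  expect_equal(res$iterations, 6L)      # 1 improving sweep + 5 stalled
})

test_that("with c1 = c2 = 0 and omega < 1 velocities decay geometrically", {
  sp <- unit_space(1L)
  st <- withr::with_seed(6, asircast:::init_swarm(sp, 1L))
  st$velocity[1, 1] <- 1
  v <- numeric(5)
  for (k in 1:5) {
    st <- pso_step(st, function(x) 0, omega = 0.5, c1 = 0, c2 = 0)
    v[k] <- st$velocity[1, 1]
  }
  expect_equal(v, 0.5^(1:5), tolerance = 1e-12)
})

test_that("cached_fitness trains identical rounded configs only once", {
  calls <- 0L
  f <- cached_fitness(function(hp) { calls <<- calls + 1L; hp$hidden_units })
  f(c(40.2, 0.1, -3, 32))
  f(c(39.8, 0.1, -3, 32))               # rounds to the same hidden = 40
  expect_identical(calls, 1L)
  f(c(41.2, 0.1, -3, 32))
  expect_identical(calls, 2L)
})

test_that("search_space validates bounds and scales", {
  expect_error(search_space(list(list(name = "a", lower = 2, upper = 1,
                                      scale = "linear", kind = "real"))),
               "lower")
  expect_error(search_space(list(list(name = "a", lower = -1, upper = 1,
                                      scale = "log10", kind = "real"))),
               "positive")
})
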