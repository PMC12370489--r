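test_that("metric hand computations are exact", {
  y <- c(1, 2, 3)
  expect_equal(mse(y, y), 0)
  expect_equal(r2(y, y), 1)
  expect_equal(mape(y, y), 0)
  expect_equal(nrmse(y, y), 0)
  expect_equal(mae(y, y), 0)

  p <- c(2, 2, 2)                     # SSres = 2, SStot = 2
  expect_equal(r2(y, p), 0)
  expect_equal(mse(y, p), 2 / 3)
  expect_equal(mae(y, p), 2 / 3)

  expect_equal(nrmse(c(0, 2), c(1, 1)), 0.5)      # rmse 1 / range 2
  expect_equal(mape(c(1, 2), c(1.1, 1.8)), 10)    # (0.1 + 0.1)/2 * 100
})

test_that("degenerate metric inputs raise instead of regularizing", {
  expect_error(mape(c(0, 2), c(1, 1)), "zero")
  expect_error(nrmse(c(2, 2), c(1, 1)), "constant")
  expect_error(r2(c(2, 2), c(1, 1)), "constant")
  expect_error(mse(numeric(0), numeric(0)), "empty")
  expect_error(mse(1:3, 1:2), "mismatch")
})

test_that("metrics agree with loop oracles on random vectors", {
  withr::with_seed(17, {
    for (rep in 1:200) {
      n <- sample(2:40, 1L)
      y <- runif(n, 0.5, 10)
      p <- y + rnorm(n)
      expect_equal(mse(y, p), oracle_mse(y, p), tolerance = 1e-12)
      expect_equal(mae(y, p), oracle_mae(y, p), tolerance = 1e-12)
      expect_equal(mape(y, p), oracle_mape(y, p), tolerance = 1e-12)
      expect_equal(r2(y, p), oracle_r2(y, p), tolerance = 1e-12)
      expect_equal(nrmse(y, p), oracle_nrmse(y, p), tolerance = 1e-12)
    }
  })
})

test_that("evaluate_forecasts pools cells and flags degenerate spreads", {
  a <- matrix(c(10, 20, 30, 40), 2, 2)
  rep0 <- evaluate_forecasts(a, a, label = "perfect")
  expect_equal(rep0$mse, 0); expect_equal(rep0$r2, 1)
  expect_equal(rep0$mape_percent, 0); expect_equal(rep0$nrmse, 0)
  expect_equal(rep0$mae, 0); expect_equal(rep0$n, 4L)

  # single (10 vs 11) pair: mse 1, mae 1, mape 10; r2/nrmse undefined
  expect_equal(mse(10, 11), 1)
  expect_equal(mae(10, 11), 1)
  expect_equal(mape(10, 11), 10)
  expect_error(evaluate_forecasts(matrix(11), matrix(10)), "constant")
  expect_error(evaluate_forecasts(matrix(1, 2, 2), matrix(1, 2, 3)), "mismatch")
})

test_that("canonical spans reproduce the three calendar folds", {
  p <- generate_panel(synth_config(seed = 1))              # 1990-2021
  folds <- make_folds(p)
  expect_length(folds, 3L)
  expect_equal(folds[[1]]$train_years, c(1990L, 2005L))
  expect_equal(folds[[1]]$val_years, c(2006L, 2010L))
  expect_equal(folds[[2]]$train_years, c(1990L, 2010L))
  expect_equal(folds[[2]]$val_years, c(2011L, 2015L))
  expect_equal(folds[[3]]$train_years, c(1990L, 2015L))
  expect_equal(folds[[3]]$val_years, c(2016L, 2020L))

  # a 1990-2020 panel gives the same folds (the trailing year is unused)
  p31 <- asir_panel(1990:2020, p$strata, p$values[1:31, ])
  expect_equal(make_folds(p31), folds)

  expect_error(make_folds(tiny_panel(18L, 2L, start_year = 1990L)), "short")
})

test_that("fold datasets honor chronology and windowing geometry", {
  p <- generate_panel(synth_config(seed = 3))
  folds <- make_folds(p)
  for (f in folds) {
    expect_lt(f$train_years[2L], f$val_years[1L])
    ds <- asircast:::fold_datasets(p, f, 10L, 5L)
    # every validation target year lies inside the fold's val block
    expect_equal(dim(ds$val$inputs)[1L], 1L)
    expect_equal(ds$val$anchor_years, f$train_years[2L])
    # training targets never touch validation years
    expect_lte(max(ds$train$anchor_years) + 5L, f$train_years[2L])
    expect_equal(ds$norm$fit_years,
                 seq.int(f$train_years[1L], f$train_years[2L]))
  }
})

test_that("cv_fitness is deterministic and ranks sensible over crippled configs", {
  p <- generate_panel(synth_config(noise_cv = 0))
  folds <- make_folds(p)
  hp_good <- hyperparams(32L, 0, 5e-3, 32L)
  f1 <- cv_fitness(hp_good, p, folds, seed = 5, inner_epochs = 10L)
  f2 <- cv_fitness(hp_good, p, folds, seed = 5, inner_epochs = 10L)
  expect_identical(f1, f2)
  hp_bad <- hyperparams(16L, 0, 1e-4, 64L)
  f_bad <- cv_fitness(hp_bad, p, folds, seed = 5, inner_epochs = 1L)
  expect_lt(f1, f_bad)
})

test_that("cv_fitness never reads beyond each fold's validation block", {
  p <- generate_panel(synth_config(noise_cv = 0.05, seed = 8))
  folds <- make_folds(p)[1:2]           # val ranges end 2010 and 2015
  hp <- hyperparams(16L, 0, 1e-3, 32L)
  base <- cv_fitness(hp, p, folds, seed = 3, inner_epochs = 3L)
  tampered <- p
  tampered$values[p$years > 2015, ] <- tampered$values[p$years > 2015, ] * 10 + 1
  expect_identical(cv_fitness(hp, tampered, folds, seed = 3, inner_epochs = 3L),
                   base)
})
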