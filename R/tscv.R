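#' Forecast-accuracy metrics
#'
#' Exact transcriptions of the five standard regression metrics: mean squared
#' error, coefficient of determination (`1 - SSres/SStot` with SStot about
#' the mean of `y`), mean absolute percentage error (in percent), normalized
#' RMSE (RMSE divided by the range of the actuals), and mean absolute error.
#' `mape` refuses zero actuals and `nrmse` refuses constant actuals rather
#' than silently regularizing.
#'
#' @param y Actual values (length n >= 1).
#' @param yhat Predictions, same length.
#' @return A scalar.
#' @name metrics
NULL

check_pair <- function(y, yhat) {
  if (length(y) == 0L) stop("empty vectors", call. = FALSE)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
}

#' @rdname metrics
#' @export
mse <- function(y, yhat) { check_pair(y, yhat); mean((y - yhat)^2) }

#' @rdname metrics
#' @export
r2 <- function(y, yhat) {
  check_pair(y, yhat)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop("r2 undefined: actual values are constant", call. = FALSE)
  1 - sum((y - yhat)^2) / sstot
}

#' @rdname metrics
#' @export
mape <- function(y, yhat) {
  check_pair(y, yhat)
  if (any(y == 0)) stop("mape undefined: actual value equal to zero", call. = FALSE)
  mean(abs((y - yhat) / y)) * 100
}

#' @rdname metrics
#' @export
nrmse <- function(y, yhat) {
  check_pair(y, yhat)
  rng <- max(y) - min(y)
  if (rng == 0) stop("nrmse undefined: actual values are constant", call. = FALSE)
  sqrt(mean((y - yhat)^2)) / rng
}

#' @rdname metrics
#' @export
mae <- function(y, yhat) { check_pair(y, yhat); mean(abs(y - yhat)) }

#' Pooled metric report for matched forecast/actual series
#'
#' Flattens all (year, stratum) cells and applies the five metrics jointly —
#' the single-headline-number convention of model comparison tables. Metrics
#' on reported tables should be computed in original rate units; the PSO
#' fitness works in z-units instead.
#'
#' @param forecasts,actuals Matrices (or vectors) of matched shape.
#' @param label Model/variant name recorded in the report.
#' @return A `metric_report` data frame row: label, mse, r2, mape_percent,
#'   nrmse, mae, n.
#' @export
evaluate_forecasts <- function(forecasts, actuals, label = "model") {
  if (!identical(dim(forecasts), dim(actuals)) ||
      length(forecasts) != length(actuals)) {
    stop("forecast/actual shape mismatch", call. = FALSE)
  }
  y <- as.numeric(actuals); p <- as.numeric(forecasts)
  out <- data.frame(label = label, mse = mse(y, p), r2 = r2(y, p),
                    mape_percent = mape(y, p), nrmse = nrmse(y, p),
                    mae = mae(y, p), n = length(y),
                    stringsAsFactors = FALSE)
  class(out) <- c("metric_report", class(out))
  out
}

#' Expanding-window cross-validation folds
#'
#' Three calendar-anchored folds with 5-year validation blocks and strictly
#' chronological train/validation splits. For a panel starting in 1990 and
#' covering at least 1990-2020 this reproduces the canonical folds
#' 1990-2005 to 2006-2010, 1990-2010 to 2011-2015, 1990-2015 to 2016-2020.
#' Generally, validation blocks end at `Y_end = start + 5 * floor((end -
#' start) / 5)` and step back 5 years per fold, so a trailing year that does
#' not complete a block (2021 in the canonical panel) is unused by CV.
#'
#' @param panel An `asir_panel`.
#' @param n_folds Number of folds (default 3).
#' @param val_len Validation block length in years (default 5).
#' @return List of `fold_spec`s, each with `train_years` and `val_years`.
#' @export
make_folds <- function(panel, n_folds = 3L, val_len = 5L) {
  y0 <- min(panel$years); y1 <- max(panel$years)
  y_end <- y0 + val_len * ((y1 - y0) %/% val_len)
  folds <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    v_hi <- y_end - val_len * (n_folds - k)
    v_lo <- v_hi - val_len + 1L
    t_hi <- v_lo - 1L
    if (t_hi - y0 + 1L < val_len) {
      stop(sprintf(
        "panel span too short for %d folds: need at least %d years from %d",
        n_folds, val_len * (n_folds + 1L), y0), call. = FALSE)
    }
    folds[[k]] <- structure(list(train_years = c(y0, t_hi),
                                 val_years = c(v_lo, v_hi)),
                            class = "fold_spec")
  }
  folds
}

#' @export
print.fold_spec <- function(x, ...) {
  cat(sprintf("<fold> train %d-%d -> val %d-%d\n",
              x$train_years[1L], x$train_years[2L],
              x$val_years[1L], x$val_years[2L]))
  invisible(x)
}

# Build the train/val windowed sets of one fold, with normalization fitted on
# the fold's training years only (no leakage). Validation windows draw their
# input context from the tail of the training years; all target years lie in
# the fold's validation block.
fold_datasets <- function(panel, fold, w, h) {
  tr_years <- seq.int(fold$train_years[1L], fold$train_years[2L])
  val_hi <- fold$val_years[2L]
  if (diff(fold$val_years) + 1L < h) {
    stop("validation block shorter than the forecast horizon", call. = FALSE)
  }
  norm <- normalize_panel(panel, fit_years = tr_years)$params
  idx_tr <- match(tr_years, panel$years)
  z_tr <- apply_norm(panel$values[idx_tr, , drop = FALSE], norm)
  tr_panel <- structure(list(years = tr_years, strata = panel$strata,
                             values = z_tr), class = "asir_panel_z")
  train_set <- make_windows(tr_panel, w, h)
  # validation windows: anchors from last train year up to val_hi - h
  idx_all <- match(seq.int(fold$train_years[1L], val_hi), panel$years)
  z_all <- apply_norm(panel$values[idx_all, , drop = FALSE], norm)
  all_panel <- structure(list(years = seq.int(fold$train_years[1L], val_hi),
                              strata = panel$strata, values = z_all),
                         class = "asir_panel_z")
  full <- make_windows(all_panel, w, h)
  keep <- full$anchor_years >= fold$train_years[2L] &
    full$anchor_years <= val_hi - h
  val_set <- subset_windows(full, which(keep))
  list(train = train_set, val = val_set, norm = norm)
}

#' Cross-validated fitness of a hyperparameter configuration
#'
#' For each fold: fit normalization on the training years, window both
#' segments, train at the inner epoch budget with early stopping on the
#' fold's validation windows, and record the validation MSE in z-units.
#' Returns the unweighted mean over folds. Seeded per fold, so identical
#' inputs give identical fitness.
#'
#' @param hp A [hyperparams].
#' @param panel An `asir_panel` in rate units.
#' @param folds Folds from [make_folds].
#' @param seed Integer seed.
#' @param w,h Window and horizon lengths.
#' @param inner_epochs Epoch budget inside the fitness (default 30; the
#'   production cap of 100 would make tuning needlessly slow).
#' @param l2 L2 coefficient passed to the trainer.
#' @param attention Passed to the trainer.
#' @return Mean validation MSE (z-units) across folds.
#' @export
cv_fitness <- function(hp, panel, folds = make_folds(panel), seed = 1L,
                       w = 10L, h = 5L, inner_epochs = 30L, l2 = 1e-4,
                       attention = TRUE) {
  scores <- vapply(seq_along(folds), function(k) {
    ds <- fold_datasets(panel, folds[[k]], w, h)
    m <- train_forecaster(ds$train, ds$val, hp,
                          seed = as.integer(seed) + k,
                          max_epochs = inner_epochs, patience = 5L,
                          l2 = l2, attention = attention)
    m$best_val_mse
  }, 0)
  mean(scores)
}

#' Write metric reports as CSV
#' @param reports A `metric_report` data frame (rows may be rbind-ed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(reports, path) {
  utils::write.csv(reports, path, row.names = FALSE)
  invisible(path)
}
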