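#' Baseline model configuration
#'
#' The four comparators with their fixed (untuned) settings: per-stratum
#' ARIMA(0,2,0); RBF-kernel support vector regression (kernel width gamma
#' 0.1, penalty C 10, epsilon 0.1); a bagged regression forest (100 trees,
#' max depth 10, min samples to split 2); and the plain LSTM — the same
#' architecture as the full forecaster minus attention, with fixed mid-range
#' hyperparameters and no swarm tuning.
#'
#' @param kind One of "arima", "svr", "rf", "lstm_plain".
#' @param ... Overrides of the per-kind defaults listed above.
#' @return A `baseline_config` list.
#' @export
baseline_config <- function(kind = c("arima", "svr", "rf", "lstm_plain"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    arima = list(order = c(0L, 2L, 0L)),
    svr = list(gamma = 0.1, cost = 10, epsilon = 0.1, iters = 500L),
    rf = list(n_trees = 100L, max_depth = 10L, min_split = 2L),
    lstm_plain = list(hp = hyperparams(40L, 0.2, 1e-3, 32L),
                      max_epochs = 100L, patience = 5L, l2 = 1e-4)
  )
  over <- list(...)
  defaults[names(over)] <- over
  structure(c(list(kind = kind), defaults), class = "baseline_config")
}

# ---- ARIMA(0,2,0) ----------------------------------------------------------
# The twice-integrated random walk has no fitted parameters; its h-step
# forecast extends the last observed linear trend:
#   yhat_{T+k} = y_T + k * (y_T - y_{T-1}).
# stats::arima is used when it fits; on failure we fall back to the identical
# closed form (drift-free second-difference extrapolation) and log it.
arima020_forecast <- function(x, h, order = c(0L, 2L, 0L)) {
  fc <- tryCatch({
    fit <- stats::arima(x, order = order, include.mean = FALSE, method = "CSS-ML")
    as.numeric(stats::predict(fit, n.ahead = h)$pred)
  }, error = function(e) {
    message("arima fit failed (", conditionMessage(e),
            "); using second-difference extrapolation")
    NULL
  })
  if (is.null(fc)) {
    n <- length(x)
    fc <- x[n] + seq_len(h) * (x[n] - x[n - 1L])
  }
  fc
}

# ---- minimal RBF epsilon-SVR ----------------------------------------------
# Authored here because no SVR package is in the pre-installed R stack.
# Dual of epsilon-insensitive SVR with the bias absorbed by centering y:
# maximize  -0.5 b' K b - epsilon ||b||_1 + y' b  over b in [-C, C]^n
# (b = alpha - alpha*), solved exactly by cyclic coordinate descent with the
# closed-form soft-threshold update per coordinate. Deterministic.
rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

svr_fit <- function(X, y, gamma = 0.1, cost = 10, epsilon = 0.1,
                    iters = 100L) {
  X <- as.matrix(X)
  K <- rbf_kernel(X, X, gamma)
  n <- nrow(X)
  b0 <- mean(y)
  yc <- y - b0
  beta <- numeric(n)
  Kbeta <- numeric(n)                    # running K %*% beta
  soft <- function(r, eps) sign(r) * pmax(abs(r) - eps, 0)
  for (sweep in seq_len(iters)) {
    delta_max <- 0
    for (i in seq_len(n)) {
      r_i <- yc[i] - (Kbeta[i] - K[i, i] * beta[i])
      new_i <- min(max(soft(r_i, epsilon) / K[i, i], -cost), cost)
      d <- new_i - beta[i]
      if (d != 0) {
        beta[i] <- new_i
        Kbeta <- Kbeta + d * K[, i]
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < 1e-8) break
  }
  list(X = X, beta = beta, b = b0, gamma = gamma)
}

svr_predict <- function(fit, Xnew) {
  drop(rbf_kernel(as.matrix(Xnew), fit$X, fit$gamma) %*% fit$beta) + fit$b
}

# ---- minimal bagged CART regression forest ---------------------------------
# Authored here because no random-forest package is in the pre-installed R
# stack. Variance-reduction splits, bootstrap resampling, mtry = floor(p/3).
tree_fit <- function(X, y, max_depth, min_split, mtry) {
  build <- function(idx, depth) {
    if (depth >= max_depth || length(idx) < min_split ||
        length(unique(y[idx])) == 1L) {
      return(list(leaf = TRUE, value = mean(y[idx])))
    }
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- NULL; best_sse <- Inf
    for (j in feats) {
      xv <- X[idx, j]
      cuts <- unique(xv)
      if (length(cuts) < 2L) next
      cuts <- (sort(cuts)[-1L] + sort(cuts)[-length(cuts)]) / 2
      for (cv in cuts) {
        l <- idx[xv <= cv]; r <- idx[xv > cv]
        if (!length(l) || !length(r)) next
        sse <- sum((y[l] - mean(y[l]))^2) + sum((y[r] - mean(y[r]))^2)
        if (sse < best_sse) { best_sse <- sse; best <- list(j = j, cut = cv) }
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, value = mean(y[idx])))
    xv <- X[idx, best$j]
    list(leaf = FALSE, j = best$j, cut = best$cut,
         left = build(idx[xv <= best$cut], depth + 1L),
         right = build(idx[xv > best$cut], depth + 1L))
  }
  build(seq_along(y), 0L)
}

tree_predict_one <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$j] <= node$cut) node$left else node$right
  }
  node$value
}

rf_fit <- function(X, y, n_trees = 100L, max_depth = 10L, min_split = 2L) {
  X <- as.matrix(X)
  mtry <- max(1L, floor(ncol(X) / 3))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    bs <- sample.int(nrow(X), nrow(X), replace = TRUE)
    trees[[t]] <- tree_fit(X[bs, , drop = FALSE], y[bs],
                           max_depth, min_split, mtry)
  }
  list(trees = trees)
}

rf_predict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  preds <- vapply(fit$trees, function(tr) {
    apply(Xnew, 1L, function(x) tree_predict_one(tr, x))
  }, numeric(nrow(Xnew)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(Xnew))
  rowMeans(preds)
}

# ---- fold evaluation harness ----------------------------------------------

# Validation cells of a fold: the h x S target block (years t_hi+1 .. t_hi+h,
# rate units) plus its anchor context. All baselines and the main model are
# scored on these identical cells.
fold_val_block <- function(panel, fold, h) {
  t_hi <- fold$train_years[2L]
  years <- t_hi + seq_len(h)
  idx <- match(years, panel$years)
  if (anyNA(idx)) stop("panel does not cover the fold's validation years", call. = FALSE)
  list(years = years, actual = panel$values[idx, , drop = FALSE])
}

#' Fit a baseline and forecast the validation block of each fold
#'
#' ARIMA forecasts each stratum univariately from the fold's training years.
#' SVR and the regression forest regress flattened lag-w feature vectors on
#' the h-step targets per stratum (one regressor per horizon step), on
#' z-normalized series, so the comparison isolates the model class. The plain
#' LSTM uses the identical windowed splits as the full forecaster. All
#' baselines are scored on the same validation cells, in rate units.
#'
#' @param config A [baseline_config].
#' @param panel An `asir_panel` in rate units.
#' @param folds Folds from [make_folds].
#' @param w,h Window and horizon.
#' @param seed Integer seed (forest resampling, LSTM training).
#' @return List with `forecasts` (per fold, h x S matrices in rate units),
#'   `actuals`, `val_years`, and `report` (pooled `metric_report`).
#' @export
fit_predict_baseline <- function(config, panel, folds = make_folds(panel),
                                 w = 10L, h = 5L, seed = 1L) {
  stopifnot(inherits(config, "baseline_config"))
  S <- ncol(panel$values)
  forecasts <- vector("list", length(folds))
  actuals <- vector("list", length(folds))
  val_years <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    fold <- folds[[k]]
    blk <- fold_val_block(panel, fold, h)
    tr_years <- seq.int(fold$train_years[1L], fold$train_years[2L])
    idx_tr <- match(tr_years, panel$years)
    pred <- matrix(0, h, S)
    if (config$kind == "arima") {
      for (s in seq_len(S)) {
        pred[, s] <- arima020_forecast(panel$values[idx_tr, s], h,
                                       order = config$order)
      }
    } else if (config$kind %in% c("svr", "rf")) {
      norm <- normalize_panel(panel, fit_years = tr_years)$params
      z_tr <- apply_norm(panel$values[idx_tr, , drop = FALSE], norm)
      pred_z <- matrix(0, h, S)
      withr::with_seed(as.integer(seed) + k, {
        for (s in seq_len(S)) {
          series <- z_tr[, s]
          n_tr <- length(series)
          anchors <- seq.int(w, n_tr - h)      # training windows within fold
          if (length(anchors) < 2L) stop("too few lag windows for baseline", call. = FALSE)
          Xl <- t(vapply(anchors, function(a) series[(a - w + 1L):a], numeric(w)))
          ctx <- matrix(series[(n_tr - w + 1L):n_tr], 1L)
          for (step in seq_len(h)) {
            yl <- series[anchors + step]
            if (config$kind == "svr") {
              fit <- svr_fit(Xl, yl, gamma = config$gamma, cost = config$cost,
                             epsilon = config$epsilon, iters = config$iters)
              pred_z[step, s] <- svr_predict(fit, ctx)
            } else {
              fit <- rf_fit(Xl, yl, n_trees = config$n_trees,
                            max_depth = config$max_depth,
                            min_split = config$min_split)
              pred_z[step, s] <- rf_predict(fit, ctx)
            }
          }
        }
      })
      pred <- invert_norm(pred_z, norm)
    } else { # lstm_plain
      ds <- fold_datasets(panel, fold, w, h)
      m <- train_forecaster(ds$train, ds$val, config$hp,
                            seed = as.integer(seed) + k,
                            max_epochs = config$max_epochs,
                            patience = config$patience, l2 = config$l2,
                            attention = FALSE)
      z_ctx <- apply_norm(panel$values[match(
        seq.int(fold$train_years[2L] - w + 1L, fold$train_years[2L]),
        panel$years), , drop = FALSE], ds$norm)
      pred <- invert_norm(forward(z_ctx, m$params, attention = FALSE), ds$norm)
    }
    pred[pred < 0] <- 0
    forecasts[[k]] <- pred
    actuals[[k]] <- blk$actual
    val_years[[k]] <- blk$years
  }
  pooled_f <- do.call(rbind, forecasts)
  pooled_a <- do.call(rbind, actuals)
  report <- evaluate_forecasts(pooled_f, pooled_a, label = config$kind)
  list(forecasts = forecasts, actuals = actuals, val_years = val_years,
       report = report)
}

#' Rank models on min-max-normalized metrics
#'
#' Per metric, scores are min-max normalized with R2 inverted (`1 - R2`) so
#' lower is uniformly better; 0 marks the best model on that metric and 1 the
#' worst. Models are ranked by mean normalized score, ties broken by label
#' order.
#'
#' @param reports A `metric_report` data frame with >= 2 rows.
#' @return Data frame with the normalized scores (`*_norm` columns), the mean
#'   score, and the rank, ordered best first.
#' @export
comparison_table <- function(reports) {
  if (nrow(reports) < 2L) stop("need at least two reports to compare", call. = FALSE)
  cols <- c("mse", "r2", "mape_percent", "nrmse", "mae")
  norm <- sapply(cols, function(cn) {
    v <- reports[[cn]]
    if (cn == "r2") v <- 1 - v          # lower-is-better uniformly
    rng <- max(v) - min(v)
    if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
  })
  norm <- matrix(norm, nrow = nrow(reports),
                 dimnames = list(NULL, paste0(cols, "_norm")))
  out <- cbind(reports[, c("label", cols)], as.data.frame(norm))
  out$mean_norm <- rowMeans(norm)
  ord <- order(out$mean_norm, out$label)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
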