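# Adam optimizer state and update, applied uniformly over the named
# weight/bias entries of a model_params list.
adam_init <- function(params, names_) {
  list(m = lapply(params[names_], function(p) p * 0),
       v = lapply(params[names_], function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

PARAM_NAMES <- c("W_f", "b_f", "W_i", "b_i", "W_o", "b_o", "W_C", "b_C",
                 "W_a", "b_a", "v", "W_y", "b_y")

#' Train the attention-LSTM forecaster
#'
#' Minimizes mean squared error over all h x S outputs (z-units) plus an L2
#' weight penalty, by Adam on seeded mini-batches. Training stops at
#' `max_epochs` or after `patience` consecutive epochs without improvement of
#' the validation MSE, whichever comes first; the returned model carries the
#' weights of the best validation epoch (best-weights restoration). With a
#' fixed seed the run is reproducible.
#'
#' @param train_set,val_set `windowed_dataset`s in z-units. `val_set` may be
#'   `NULL`, in which case early stopping is disabled and training runs the
#'   full `max_epochs`.
#' @param hp A [hyperparams].
#' @param seed Integer seed controlling weight initialization, batch
#'   shuffling and dropout masks.
#' @param max_epochs Epoch cap (default 100).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param l2 L2 regularization coefficient (default 1e-4).
#' @param attention Use attention pooling (default) or last-hidden-state
#'   pooling (the plain-LSTM ablation variant).
#' @param normalization Optional `norm_params` to attach to the model (used
#'   by [forecast_next]).
#' @return A `trained_model`: `params`, `hyperparams`, `normalization`,
#'   `history` (per-epoch train loss and validation MSE), `stop_epoch`,
#'   `best_epoch`, `seed`, `attention`.
#' @export
train_forecaster <- function(train_set, val_set = NULL, hp = hyperparams(),
                             seed = 1L, max_epochs = 100L, patience = 5L,
                             l2 = 1e-4, attention = TRUE,
                             normalization = NULL) {
  n <- dim(train_set$inputs)[1L]
  if (is.null(n) || n == 0L) stop("empty training set", call. = FALSE)
  w <- train_set$w; S <- dim(train_set$inputs)[3L]; h <- train_set$h
  Y <- flatten_targets(train_set$targets)
  Yval <- if (!is.null(val_set)) flatten_targets(val_set$targets)
  params <- init_model_params(S, hp$hidden_units, h, seed = seed)
  opt <- adam_init(params, PARAM_NAMES)
  hist_train <- numeric(0); hist_val <- numeric(0)
  best_val <- Inf; best_params <- params; best_epoch <- 0L; stall <- 0L
  stop_epoch <- 0L
  withr::with_seed(as.integer(seed) + 1L, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / hp$batch_size))
      ep_loss <- 0
      for (b in batches) {
        Xb <- train_set$inputs[b, , , drop = FALSE]
        Yb <- Y[b, , drop = FALSE]
        mask <- NULL
        if (hp$dropout_rate > 0) {
          mask <- lapply(seq_len(w), function(t) {
            matrix(stats::runif(length(b) * hp$hidden_units) >= hp$dropout_rate,
                   length(b), hp$hidden_units) / (1 - hp$dropout_rate)
          })
        }
        fb <- forward_backward(Xb, params, Yb, dropout_mask = mask,
                               attention = attention, l2 = l2)
        if (!is.finite(fb$loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
               call. = FALSE)
        }
        upd <- adam_update(params, fb$grads, opt, hp$learning_rate)
        params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + fb$loss * length(b)
      }
      hist_train <- c(hist_train, ep_loss / n)
      stop_epoch <- epoch
      if (!is.null(val_set)) {
        pv <- predict_batch(val_set$inputs, params, attention = attention)
        vmse <- mean((pv - Yval)^2)
        hist_val <- c(hist_val, vmse)
        if (vmse < best_val - 1e-12) {
          best_val <- vmse; best_params <- params
          best_epoch <- epoch; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      } else {
        best_params <- params; best_epoch <- epoch
      }
    }
  })
  structure(list(params = best_params, hyperparams = hp,
                 normalization = normalization,
                 history = list(train_loss = hist_train, val_mse = hist_val),
                 stop_epoch = stop_epoch, best_epoch = best_epoch,
                 best_val_mse = if (is.finite(best_val)) best_val else NA_real_,
                 seed = as.integer(seed), attention = attention,
                 l2 = l2, w = w, h = h),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> hidden = %d, attention = %s, stopped at epoch %d (best %d)\n",
    x$hyperparams$hidden_units, x$attention, x$stop_epoch, x$best_epoch))
  invisible(x)
}

#' Forecast the next h years of a panel
#'
#' Normalizes the last w years of the panel with the model's stored
#' normalization parameters, runs one deterministic forward pass, and
#' denormalizes back to rate units. Forecast years are labelled
#' `last_year + 1 ... last_year + h`.
#'
#' @param panel An [asir_panel] in rate units covering at least w years.
#' @param model A `trained_model` carrying `normalization` fitted on matching
#'   strata.
#' @param h Horizon; defaults to the model's trained horizon and must not
#'   exceed it.
#' @return Data frame in the long CSV dialect (year, sex, age_group, value).
#' @export
forecast_next <- function(panel, model, h = model$h) {
  stopifnot(inherits(model, "trained_model"))
  np <- model$normalization
  if (is.null(np)) stop("model has no normalization parameters attached", call. = FALSE)
  if (!identical(paste(panel$strata$sex, panel$strata$age_group),
                 paste(np$strata$sex, np$strata$age_group))) {
    stop("panel strata do not match the model's normalization strata", call. = FALSE)
  }
  if (h > model$h) stop("h exceeds the model's trained horizon", call. = FALSE)
  Tn <- length(panel$years)
  if (Tn < model$w) {
    stop(sprintf("panel too short: need at least w = %d years", model$w), call. = FALSE)
  }
  z <- apply_norm(panel$values[(Tn - model$w + 1L):Tn, , drop = FALSE], np)
  pred_z <- forward(z, model$params, attention = model$attention)
  pred <- invert_norm(pred_z[seq_len(h), , drop = FALSE], np)
  pred[pred < 0] <- 0                   # rates cannot be negative
  years <- max(panel$years) + seq_len(h)
  S <- nrow(panel$strata)
  data.frame(
    year = rep(years, each = S),
    sex = rep(panel$strata$sex, times = h),
    age_group = rep(panel$strata$age_group, times = h),
    value = as.vector(t(pred)),
    stringsAsFactors = FALSE
  )
}

#' Save a trained model as a text bundle
#'
#' Writes `meta.json` (hyperparameters, normalization, history, seed, shapes)
#' and `weights.csv` (one row per parameter entry) under `dir`.
#'
#' @param model A `trained_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- do.call(rbind, lapply(PARAM_NAMES, function(nm) {
    p <- model$params[[nm]]
    data.frame(param = nm, index = seq_along(p), value = as.numeric(p),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(wt, file.path(dir, "weights.csv"), row.names = FALSE)
  np <- model$normalization
  meta <- list(
    package = "asircast",
    hyperparams = unclass(model$hyperparams),
    shapes = list(S = model$params$S, hidden = model$params$hidden,
                  h = model$params$h, w = model$w),
    attention = model$attention, l2 = model$l2, seed = model$seed,
    stop_epoch = model$stop_epoch, best_epoch = model$best_epoch,
    best_val_mse = model$best_val_mse,
    history = model$history,
    normalization = if (!is.null(np)) {
      list(mu = unname(np$mu), sigma = unname(np$sigma),
           fit_years = np$fit_years, sex = np$strata$sex,
           age_group = np$strata$age_group)
    }
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a model bundle written by [save_model]
#' @param dir Bundle directory.
#' @return A `trained_model`.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  wt <- utils::read.csv(file.path(dir, "weights.csv"), stringsAsFactors = FALSE)
  S <- meta$shapes$S; hidden <- meta$shapes$hidden; h <- meta$shapes$h
  params <- init_model_params(S, hidden, h, zero = TRUE)
  for (nm in PARAM_NAMES) {
    vals <- wt$value[wt$param == nm][order(wt$index[wt$param == nm])]
    if (is.matrix(params[[nm]])) {
      params[[nm]] <- matrix(vals, nrow(params[[nm]]), ncol(params[[nm]]))
    } else {
      params[[nm]] <- vals
    }
  }
  np <- NULL
  if (!is.null(meta$normalization)) {
    strata <- data.frame(sex = meta$normalization$sex,
                         age_group = meta$normalization$age_group,
                         stringsAsFactors = FALSE)
    np <- structure(list(mu = meta$normalization$mu,
                         sigma = meta$normalization$sigma,
                         fit_years = as.integer(meta$normalization$fit_years),
                         strata = strata),
                    class = "norm_params")
  }
  hp <- do.call(hyperparams, as.list(meta$hyperparams))
  structure(list(params = params, hyperparams = hp, normalization = np,
                 history = meta$history, stop_epoch = meta$stop_epoch,
                 best_epoch = meta$best_epoch, best_val_mse = meta$best_val_mse,
                 seed = meta$seed, attention = meta$attention, l2 = meta$l2,
                 w = meta$shapes$w, h = h),
            class = "trained_model")
}
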