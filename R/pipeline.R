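#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end flow: data source, window geometry,
#' swarm settings, training budgets, the ablation variant, and the output
#' directory. Every run writes a `manifest.json` echoing the resolved
#' configuration and seeds so it is fully reconstructible.
#'
#' @param input Path to a long-format CSV panel, or `NULL` to simulate.
#' @param synth A [synth_config] used when `input` is `NULL`.
#' @param w,h Window and horizon lengths (defaults 10 and 5).
#' @param n_particles,max_iter,pso_patience Swarm settings (defaults 10, 50, 5).
#' @param max_epochs,patience Final-training budget (defaults 100, 5).
#' @param inner_epochs Epoch budget inside the CV fitness (default 30).
#' @param l2 L2 regularization coefficient (default 1e-4).
#' @param fixed_hp Hyperparameters used by non-tuned variants: midpoints of
#'   the search ranges (hidden 40, dropout 0.2, lr 1e-3, batch 32).
#' @param variant One of "full", "lstm_only", "lstm_attention", "lstm_pso".
#' @param seed Master seed.
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, synth = synth_config(), w = 10L, h = 5L,
                       n_particles = 10L, max_iter = 50L, pso_patience = 5L,
                       max_epochs = 100L, patience = 5L, inner_epochs = 30L,
                       l2 = 1e-4, fixed_hp = hyperparams(40L, 0.2, 1e-3, 32L),
                       variant = c("full", "lstm_only", "lstm_attention",
                                   "lstm_pso"),
                       seed = 1L, out_dir = NULL) {
  variant <- match.arg(variant)
  stopifnot(w >= 1L, h >= 1L, n_particles >= 1L, max_iter >= 1L,
            max_epochs >= 1L, inner_epochs >= 1L, l2 >= 0)
  structure(list(input = input, synth = synth, w = as.integer(w),
                 h = as.integer(h), n_particles = as.integer(n_particles),
                 max_iter = as.integer(max_iter),
                 pso_patience = as.integer(pso_patience),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 inner_epochs = as.integer(inner_epochs), l2 = l2,
                 fixed_hp = fixed_hp, variant = variant,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

variant_uses_attention <- function(variant) {
  variant %in% c("full", "lstm_attention")
}
variant_uses_pso <- function(variant) {
  variant %in% c("full", "lstm_pso")
}

load_or_simulate <- function(config) {
  if (!is.null(config$input)) read_panel(config$input) else generate_panel(config$synth)
}

# Train the given configuration on each fold and score it on the identical
# validation cells used by every other variant/baseline (rate units).
evaluate_variant <- function(panel, folds, hp, w, h, seed, attention,
                             max_epochs, patience, l2, label) {
  forecasts <- vector("list", length(folds))
  actuals <- vector("list", length(folds))
  val_mses <- numeric(length(folds))
  for (k in seq_along(folds)) {
    fold <- folds[[k]]
    ds <- fold_datasets(panel, fold, w, h)
    m <- train_forecaster(ds$train, ds$val, hp, seed = as.integer(seed) + k,
                          max_epochs = max_epochs, patience = patience,
                          l2 = l2, attention = attention)
    val_mses[k] <- m$best_val_mse
    ctx_years <- seq.int(fold$train_years[2L] - w + 1L, fold$train_years[2L])
    z_ctx <- apply_norm(panel$values[match(ctx_years, panel$years), ,
                                     drop = FALSE], ds$norm)
    pred <- invert_norm(forward(z_ctx, m$params, attention = attention), ds$norm)
    pred[pred < 0] <- 0
    forecasts[[k]] <- pred
    actuals[[k]] <- fold_val_block(panel, fold, h)$actual
  }
  report <- evaluate_forecasts(do.call(rbind, forecasts),
                               do.call(rbind, actuals), label = label)
  list(report = report, forecasts = forecasts, actuals = actuals,
       val_mse = mean(val_mses))
}

#' Run the end-to-end forecasting pipeline
#'
#' Load or simulate the panel, build the expanding-window folds, tune
#' hyperparameters by PSO (unless the variant disables it), train the final
#' model on all years with early stopping on the most recent windows,
#' forecast the next h years, and evaluate the configuration on the CV folds.
#' When `config$out_dir` is set, writes the model bundle, forecast CSV,
#' metric report, PSO trace and a manifest.
#'
#' @param config A [run_config].
#' @return List with `model`, `forecast` (long data frame), `report`,
#'   `cv_val_mse`, `hp`, `pso` (trace or `NULL`), `folds`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  panel <- load_or_simulate(config)
  folds <- make_folds(panel)
  attention <- variant_uses_attention(config$variant)

  pso_res <- NULL
  if (variant_uses_pso(config$variant)) {
    fitness <- cached_fitness(function(hp) {
      cv_fitness(hp, panel, folds, seed = config$seed, w = config$w,
                 h = config$h, inner_epochs = config$inner_epochs,
                 l2 = config$l2, attention = attention)
    })
    pso_res <- pso_optimize(fitness, search_space(),
                            n_particles = config$n_particles,
                            max_iter = config$max_iter,
                            patience = config$pso_patience,
                            seed = config$seed)
    hp <- pso_res$best_decoded
  } else {
    hp <- config$fixed_hp
  }

  # fold-level evaluation of the chosen configuration (rate units)
  ev <- evaluate_variant(panel, folds, hp, config$w, config$h, config$seed,
                         attention, config$max_epochs, config$patience,
                         config$l2, label = config$variant)

  # final fit on all years: normalization on the full span, latest windows
  # held out for early stopping
  nrm <- normalize_panel(panel)
  all_windows <- make_windows(nrm$panel, config$w, config$h)
  n_all <- dim(all_windows$inputs)[1L]
  n_val <- max(1L, min(3L, n_all - 1L))
  if (n_all >= 2L) {
    tr <- subset_windows(all_windows, seq_len(n_all - n_val))
    va <- subset_windows(all_windows, seq.int(n_all - n_val + 1L, n_all))
  } else {
    tr <- all_windows; va <- NULL
  }
  model <- train_forecaster(tr, va, hp, seed = config$seed,
                            max_epochs = config$max_epochs,
                            patience = config$patience, l2 = config$l2,
                            attention = attention,
                            normalization = nrm$params)
  fc <- forecast_next(panel, model, h = config$h)

  manifest <- list(
    package = "asircast",
    version = as.character(utils::packageVersion("asircast")),
    variant = config$variant, seed = config$seed,
    w = config$w, h = config$h,
    attention = attention, pso = variant_uses_pso(config$variant),
    swarm = list(n_particles = config$n_particles,
                 max_iter = config$max_iter, patience = config$pso_patience),
    training = list(max_epochs = config$max_epochs, patience = config$patience,
                    l2 = config$l2, inner_epochs = config$inner_epochs),
    hyperparams = unclass(hp),
    input = if (is.null(config$input)) "synthetic" else config$input,
    folds = lapply(folds, function(f) list(train = f$train_years,
                                           val = f$val_years))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(model, file.path(config$out_dir, "model"))
    utils::write.csv(fc, file.path(config$out_dir, "forecast.csv"),
                     row.names = FALSE)
    write_metric_report(ev$report, file.path(config$out_dir, "metrics.csv"))
    if (!is.null(pso_res)) {
      utils::write.csv(pso_res$trace, file.path(config$out_dir, "pso_trace.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(model = model, forecast = fc, report = ev$report,
       cv_val_mse = ev$val_mse, hp = hp, pso = pso_res, folds = folds,
       panel = panel, manifest = manifest)
}

#' Run the four-variant ablation
#'
#' Evaluates `lstm_only`, `lstm_attention`, `lstm_pso` and `full` on
#' bit-identical folds, normalization and seeds, producing one metric-report
#' row per variant (rate units, pooled over folds) plus each variant's mean
#' CV validation MSE in z-units.
#'
#' @param config A [run_config]; its `variant` field is ignored.
#' @return List with `table` (4-row `metric_report`), `val_mse` (named
#'   vector, z-units), and `hp` (per-variant hyperparameters used).
#' @export
run_ablation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  panel <- load_or_simulate(config)
  folds <- make_folds(panel)
  variants <- c("lstm_only", "lstm_attention", "lstm_pso", "full")
  reports <- list(); val_mse <- numeric(0); hps <- list()
  for (v in variants) {
    attention <- variant_uses_attention(v)
    if (variant_uses_pso(v)) {
      fitness <- cached_fitness(function(hp) {
        cv_fitness(hp, panel, folds, seed = config$seed, w = config$w,
                   h = config$h, inner_epochs = config$inner_epochs,
                   l2 = config$l2, attention = attention)
      })
      hp <- pso_optimize(fitness, search_space(),
                         n_particles = config$n_particles,
                         max_iter = config$max_iter,
                         patience = config$pso_patience,
                         seed = config$seed)$best_decoded
    } else {
      hp <- config$fixed_hp
    }
    ev <- evaluate_variant(panel, folds, hp, config$w, config$h, config$seed,
                           attention, config$max_epochs, config$patience,
                           config$l2, label = v)
    reports[[v]] <- ev$report
    val_mse[v] <- ev$val_mse
    hps[[v]] <- hp
  }
  tbl <- do.call(rbind, reports)
  rownames(tbl) <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metric_report(tbl, file.path(config$out_dir, "ablation.csv"))
  }
  list(table = tbl, val_mse = val_mse, hp = hps, folds = folds)
}
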