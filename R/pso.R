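#' Hyperparameter search space
#'
#' Per-dimension bounds, scale and kind. The default is the four-dimensional
#' forecaster space: hidden units (integer, 16-64), dropout rate (real,
#' 0-0.4), learning rate (real, 1e-4 to 1e-2, searched in log10 space), batch
#' size (integer, 16-64). Internal particle coordinates are linear except for
#' log10-scaled dimensions, which live in log10 units.
#'
#' @param dims List of per-dimension specs, each a list with `name`, `lower`,
#'   `upper`, `scale` ("linear" or "log10") and `kind` ("integer" or "real").
#' @return A `search_space` object.
#' @export
search_space <- function(dims = default_dims()) {
  for (d in dims) {
    stopifnot(all(c("name", "lower", "upper", "scale", "kind") %in% names(d)))
    if (d$lower >= d$upper) stop("lower must be < upper for ", d$name, call. = FALSE)
    if (d$scale == "log10" && d$lower <= 0) {
      stop("log10 scale requires positive bounds for ", d$name, call. = FALSE)
    }
    if (!d$scale %in% c("linear", "log10")) stop("unknown scale", call. = FALSE)
    if (!d$kind %in% c("integer", "real")) stop("unknown kind", call. = FALSE)
  }
  structure(list(dims = dims), class = "search_space")
}

default_dims <- function() {
  list(
    list(name = "hidden_units", lower = 16, upper = 64, scale = "linear", kind = "integer"),
    list(name = "dropout_rate", lower = 0.0, upper = 0.4, scale = "linear", kind = "real"),
    list(name = "learning_rate", lower = 1e-4, upper = 1e-2, scale = "log10", kind = "real"),
    list(name = "batch_size", lower = 16, upper = 64, scale = "linear", kind = "integer")
  )
}

# Internal-coordinate bounds (log dims in log10 units)
internal_bounds <- function(space) {
  lo <- vapply(space$dims, function(d) if (d$scale == "log10") log10(d$lower) else d$lower, 0)
  hi <- vapply(space$dims, function(d) if (d$scale == "log10") log10(d$upper) else d$upper, 0)
  list(lower = lo, upper = hi)
}

#' Decode an internal particle position into hyperparameters
#'
#' log10 dimensions are exponentiated; integer dimensions are rounded to the
#' nearest integer and clipped to their bounds. For the default space the
#' result is a valid [hyperparams].
#'
#' @param position Numeric vector in internal coordinates.
#' @param space A [search_space].
#' @return Named list of decoded values; a [hyperparams] object when the
#'   space has the default four dimension names.
#' @export
decode_position <- function(position, space = search_space()) {
  stopifnot(length(position) == length(space$dims))
  out <- list()
  for (j in seq_along(space$dims)) {
    d <- space$dims[[j]]
    x <- position[j]
    if (d$scale == "log10") x <- 10^x
    if (d$kind == "integer") x <- min(max(round(x), ceiling(d$lower)), floor(d$upper))
    else x <- min(max(x, d$lower), d$upper)
    out[[d$name]] <- x
  }
  nm <- vapply(space$dims, `[[`, "", "name")
  if (identical(sort(nm), sort(c("hidden_units", "dropout_rate",
                                 "learning_rate", "batch_size")))) {
    out <- do.call(hyperparams, out)
  }
  out
}

#' Linearly annealed inertia weight
#'
#' `0.9 - 0.4 * (iter / max_iter)`: 0.9 at the start, 0.5 at the final
#' iteration, monotone decreasing in between.
#'
#' @param iter Iteration counter, `0 <= iter <= max_iter`.
#' @param max_iter Total iterations, `> 0`.
#' @return The inertia weight.
#' @export
inertia_at <- function(iter, max_iter) {
  stopifnot(max_iter > 0, iter >= 0, iter <= max_iter)
  0.9 - 0.4 * (iter / max_iter)
}

# Build a fresh swarm: positions uniform in internal bounds, velocities zero.
init_swarm <- function(space, n_particles) {
  b <- internal_bounds(space)
  ndim <- length(b$lower)
  pos <- matrix(stats::runif(n_particles * ndim), n_particles, ndim)
  pos <- sweep(sweep(pos, 2L, b$upper - b$lower, "*"), 2L, b$lower, "+")
  structure(list(
    position = pos,
    velocity = matrix(0, n_particles, ndim),
    pbest_pos = pos,
    pbest_score = rep(Inf, n_particles),
    gbest_pos = pos[1L, ],
    gbest_score = Inf,
    iter = 0L, stall = 0L, space = space
  ), class = "swarm_state")
}

#' One particle-swarm iteration
#'
#' Evaluates the fitness of every particle at its current position, updates
#' personal and global bests, then moves each particle by the velocity rule
#' `v <- omega v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, with `r1`, `r2`
#' scalar uniforms drawn per particle per term from `rand_fn`. Velocities are
#' clamped to half the per-dimension range width (the classic Vmax = Xmax
#' rule) and positions clipped to bounds. A fitness call that errors scores
#' the particle `+Inf` (robustness over abort).
#'
#' @param state A `swarm_state`.
#' @param fitness Function from internal position vector to a finite score.
#' @param omega Inertia weight.
#' @param c1,c2 Cognitive and social acceleration coefficients (default 2.0).
#' @param rand_fn Function `n -> n` uniforms in (0, 1); injectable for exact
#'   hand-computed tests. Defaults to `runif`.
#' @return The updated `swarm_state`.
#' @export
pso_step <- function(state, fitness, omega, c1 = 2.0, c2 = 2.0,
                     rand_fn = stats::runif) {
  b <- internal_bounds(state$space)
  np <- nrow(state$position); ndim <- ncol(state$position)
  improved <- FALSE
  for (i in seq_len(np)) {
    score <- tryCatch(fitness(state$position[i, ]), error = function(e) {
      warning("fitness evaluation failed; particle scored +Inf: ",
              conditionMessage(e), call. = FALSE)
      Inf
    })
    if (!is.finite(score)) score <- Inf
    if (score < state$pbest_score[i]) {
      state$pbest_score[i] <- score
      state$pbest_pos[i, ] <- state$position[i, ]
    }
    if (score < state$gbest_score - 1e-9) improved <- TRUE
    if (score < state$gbest_score) {
      state$gbest_score <- score
      state$gbest_pos <- state$position[i, ]
    }
  }
  vmax <- (b$upper - b$lower) / 2
  for (i in seq_len(np)) {
    r1 <- rand_fn(1L); r2 <- rand_fn(1L)
    v <- omega * state$velocity[i, ] +
      c1 * r1 * (state$pbest_pos[i, ] - state$position[i, ]) +
      c2 * r2 * (state$gbest_pos - state$position[i, ])
    v <- pmin(pmax(v, -vmax), vmax)
    x <- pmin(pmax(state$position[i, ] + v, b$lower), b$upper)
    state$velocity[i, ] <- v
    state$position[i, ] <- x
  }
  state$iter <- state$iter + 1L
  state$stall <- if (improved) 0L else state$stall + 1L
  state
}

#' Particle swarm optimization
#'
#' Minimizes `fitness` over `space` with `n_particles` particles for at most
#' `max_iter` iterations, inertia annealed linearly from 0.9 to 0.5
#' ([inertia_at]) and `c1 = c2 = 2`. Stops early when the global best has not
#' improved by more than 1e-9 for `patience` consecutive iterations. Fully
#' deterministic for a fixed seed.
#'
#' @param fitness Function from internal position vector to score (lower is
#'   better).
#' @param space A [search_space].
#' @param n_particles Swarm size (default 10).
#' @param max_iter Iteration cap (default 50).
#' @param patience Stall iterations before stopping (default 5).
#' @param seed Integer seed.
#' @param c1,c2 Acceleration coefficients (default 2.0).
#' @return List with `best_position` (internal), `best_decoded`,
#'   `best_score`, and `trace` (data frame: iteration, best_score).
#' @export
pso_optimize <- function(fitness, space = search_space(), n_particles = 10L,
                         max_iter = 50L, patience = 5L, seed = 1L,
                         c1 = 2.0, c2 = 2.0) {
  stopifnot(n_particles >= 1L, max_iter >= 1L)
  withr::with_seed(as.integer(seed), {
    state <- init_swarm(space, n_particles)
    trace <- data.frame(iteration = integer(0), best_score = numeric(0))
    for (it in seq_len(max_iter)) {
      omega <- inertia_at(it, max_iter)
      state <- pso_step(state, fitness, omega, c1 = c1, c2 = c2)
      trace <- rbind(trace, data.frame(iteration = it,
                                       best_score = state$gbest_score))
      if (state$stall >= patience) break
    }
    list(best_position = state$gbest_pos,
         best_decoded = decode_position(state$gbest_pos, space),
         best_score = state$gbest_score,
         trace = trace,
         iterations = state$iter)
  })
}

#' Cached hyperparameter fitness wrapper
#'
#' PSO treats integer dimensions as continuous and rounds at decode time, so
#' distinct internal positions can decode to the same hyperparameters. This
#' wrapper memoizes `fit_fn` on the decoded values so identical configurations
#' are trained once.
#'
#' @param fit_fn Function taking a decoded hyperparameter list and returning a
#'   score.
#' @param space The [search_space] used for decoding.
#' @return A fitness function over internal positions, with the cache
#'   environment attached as attribute `"cache"`.
#' @export
cached_fitness <- function(fit_fn, space = search_space()) {
  cache <- new.env(parent = emptyenv())
  f <- function(position) {
    hp <- decode_position(position, space)
    key <- paste(vapply(unclass(hp), function(x) format(x, digits = 12), ""),
                 collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fit_fn(hp)
    assign(key, val, envir = cache)
    val
  }
  attr(f, "cache") <- cache
  f
}
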