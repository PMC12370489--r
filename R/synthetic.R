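#' Configuration for the synthetic stratified-incidence generator
#'
#' The generator emulates the shape and gross statistical structure of a
#' GBD-style ASIR extract: annual rates for 2 sexes x 12 five-year age groups
#' over about three decades. The expectation surface is
#' \deqn{E[x_{t,(sex,a)}] = base \cdot slope^{a} \cdot roll(a) \cdot
#'       ratio(sex) \cdot trend_{a}(t)}
#' a monotone log-linear age gradient with a late-age rolloff (the open-ended
#' oldest band sits well below its neighbour in real extracts), a constant
#' male/female ratio, and a per-stratum logistic rise-and-plateau trend in
#' time. Observed values multiply the expectation by mean-one lognormal noise.
#'
#' @param n_years Number of consecutive years (default 32, i.e. 1990-2021).
#' @param start_year First calendar year (default 1990).
#' @param age_groups Ordered age-band labels (default the 12 canonical bands
#'   40-44 ... 95+).
#' @param sexes Sex labels, male first (default `c("male", "female")`).
#' @param base_rate_40 Female rate scale for the youngest band, per 100,000
#'   (default 6).
#' @param age_log_slope Per-band increment of log expected rate (default 0.42,
#'   i.e. roughly x1.5 per 5-year band, spanning two orders of magnitude over
#'   the 12 bands as real lung-cancer ASIR does).
#' @param sex_ratio Male/female expected-rate ratio (default 2.2).
#' @param rolloff Multiplier applied to the oldest (open-ended) band
#'   (default 0.45; set to 1 to disable).
#' @param trend_low,trend_high Trend multiplier before/after the logistic
#'   rise (defaults 0.7 and 1.3: a ~85% rise over the span, plateauing).
#' @param trend_tau Logistic time scale in years (default 4).
#' @param trend_mid_offset Years after `start_year` at which the youngest
#'   band's trend midpoint sits (default 8); midpoints shift one further year
#'   per age band so different strata have genuinely different informative
#'   periods.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (default 0.05; 0 gives the noiseless expectation exactly).
#' @param seed Integer seed for the noise draw (default 1).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_years = 32L, start_year = 1990L,
                         age_groups = DEFAULT_AGE_GROUPS,
                         sexes = DEFAULT_SEXES,
                         base_rate_40 = 6, age_log_slope = 0.42,
                         sex_ratio = 2.2, rolloff = 0.45,
                         trend_low = 0.7, trend_high = 1.3,
                         trend_tau = 4, trend_mid_offset = 8,
                         noise_cv = 0.05, seed = 1L) {
  cfg <- list(n_years = as.integer(n_years), start_year = as.integer(start_year),
              age_groups = as.character(age_groups), sexes = as.character(sexes),
              base_rate_40 = base_rate_40, age_log_slope = age_log_slope,
              sex_ratio = sex_ratio, rolloff = rolloff,
              trend_low = trend_low, trend_high = trend_high,
              trend_tau = trend_tau, trend_mid_offset = trend_mid_offset,
              noise_cv = noise_cv, seed = as.integer(seed))
  if (cfg$n_years < 16L) stop("n_years must be >= 16 (w = 10, h = 5 default)", call. = FALSE)
  if (cfg$base_rate_40 <= 0 || cfg$sex_ratio <= 0 || cfg$rolloff <= 0 ||
      cfg$trend_low <= 0 || cfg$trend_high <= 0 || cfg$trend_tau <= 0) {
    stop("rate/trend parameters must be positive", call. = FALSE)
  }
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (length(cfg$sexes) < 1L || length(cfg$age_groups) < 1L) {
    stop("need at least one sex and one age group", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Noiseless expectation surface of the synthetic generator
#'
#' @param config A [synth_config].
#' @return An [asir_panel] holding the expectation of [generate_panel] cell
#'   by cell. `generate_panel(config)` with `noise_cv = 0` equals this
#'   exactly; with noise, the empirical mean over seeds converges to it.
#' @export
expected_surface <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  years <- config$start_year + seq_len(config$n_years) - 1L
  n_age <- length(config$age_groups)
  strata <- data.frame(
    sex = rep(config$sexes, each = n_age),
    age_group = rep(config$age_groups, times = length(config$sexes)),
    stringsAsFactors = FALSE
  )
  values <- matrix(0, config$n_years, nrow(strata))
  for (s in seq_len(nrow(strata))) {
    ai <- match(strata$age_group[s], config$age_groups)
    level <- config$base_rate_40 * exp(config$age_log_slope * (ai - 1L))
    if (ai == n_age && n_age > 1L) level <- level * config$rolloff
    if (strata$sex[s] == config$sexes[1L] && length(config$sexes) > 1L) {
      level <- level * config$sex_ratio
    }
    mid <- config$start_year + config$trend_mid_offset + (ai - 1L)
    trend <- config$trend_low + (config$trend_high - config$trend_low) /
      (1 + exp(-(years - mid) / config$trend_tau))
    values[, s] <- level * trend
  }
  asir_panel(years, strata, values)
}

#' Generate a synthetic stratified incidence panel
#'
#' Multiplies the [expected_surface] by i.i.d. mean-one lognormal noise with
#' coefficient of variation `noise_cv`. Identical seeds give bitwise-identical
#' panels; `noise_cv = 0` returns the expectation regardless of seed.
#'
#' @param config A [synth_config].
#' @return An [asir_panel].
#' @export
generate_panel <- function(config) {
  surf <- expected_surface(config)
  if (config$noise_cv == 0) return(surf)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  noise <- withr::with_seed(config$seed, {
    matrix(stats::rlnorm(length(surf$values),
                         meanlog = -sdlog^2 / 2, sdlog = sdlog),
           nrow(surf$values), ncol(surf$values))
  })
  asir_panel(surf$years, surf$strata, surf$values * noise)
}
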