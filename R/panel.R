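# Canonical age-group labels: 5-year bands from 40-44 up to 90-94, then the
# open-ended 95+ band, matching the GBD results-tool stratification.
DEFAULT_AGE_GROUPS <- c(
  "40-44", "45-49", "50-54", "55-59", "60-64", "65-69",
  "70-74", "75-79", "80-84", "85-89", "90-94", "95+"
)
DEFAULT_SEXES <- c("male", "female")

#' Stratified incidence panel
#'
#' An `asir_panel` holds a T x S matrix of annual age-standardized incidence
#' rates (new cases per 100,000 person-years), with one column per
#' (sex, age-group) stratum and one row per calendar year. Years must be
#' consecutive; values must be complete and non-negative. The canonical
#' stratum order is sex-major (male block first), age ascending, so column
#' indices are stable across runs.
#'
#' @param years Integer vector of consecutive, strictly increasing calendar
#'   years.
#' @param strata Data frame with character columns `sex` and `age_group`;
#'   one row per stratum, no duplicates.
#' @param values Numeric matrix, `length(years)` rows by `nrow(strata)`
#'   columns, all entries finite and `>= 0`.
#' @return An object of class `asir_panel` with fields `years`, `strata`,
#'   `values`.
#' @export
asir_panel <- function(years, strata, values) {
  years <- as.integer(years)
  if (length(years) == 0L || any(diff(years) != 1L)) {
    stop("`years` must be non-empty, strictly increasing with step 1", call. = FALSE)
  }
  strata <- as.data.frame(strata, stringsAsFactors = FALSE)
  if (!all(c("sex", "age_group") %in% names(strata))) {
    stop("`strata` needs columns `sex` and `age_group`", call. = FALSE)
  }
  strata$sex <- as.character(strata$sex)
  strata$age_group <- as.character(strata$age_group)
  key <- paste(strata$sex, strata$age_group, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (sex, age_group) strata: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(values)
  if (nrow(values) != length(years) || ncol(values) != nrow(strata)) {
    stop(sprintf("`values` must be %d x %d (years x strata), got %d x %d",
                 length(years), nrow(strata), nrow(values), ncol(values)),
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` contains missing or non-finite entries", call. = FALSE)
  }
  if (any(values < 0)) stop("`values` contains negative rates", call. = FALSE)
  storage.mode(values) <- "double"
  colnames(values) <- key
  rownames(values) <- as.character(years)
  structure(list(years = years, strata = strata, values = values),
            class = "asir_panel")
}

#' @export
print.asir_panel <- function(x, ...) {
  cat(sprintf("<asir_panel> %d years (%d-%d) x %d strata = %d records\n",
              length(x$years), min(x$years), max(x$years),
              nrow(x$strata), length(x$values)))
  invisible(x)
}

#' @export
dim.asir_panel <- function(x) dim(x$values)

stratum_labels <- function(panel) {
  paste(panel$strata$sex, panel$strata$age_group, sep = "|")
}

# Sort strata into the canonical sex-major (male first), age-ascending order.
# Age order follows the order of first appearance when labels are not in the
# default set; default labels use the canonical band order.
canonical_stratum_order <- function(strata, sexes = DEFAULT_SEXES,
                                    age_groups = NULL) {
  sex_rank <- match(strata$sex, union(sexes, unique(strata$sex)))
  if (is.null(age_groups)) {
    age_groups <- union(DEFAULT_AGE_GROUPS, unique(strata$age_group))
  }
  age_rank <- match(strata$age_group, age_groups)
  order(sex_rank, age_rank)
}

#' Read a stratified incidence panel from a long-format CSV
#'
#' Expects the GBD results-tool dialect: one row per (year, sex, age group)
#' with a rate value. Column names are configurable through `schema`; extra
#' columns (e.g. `upper`, `lower`) are ignored. The table is validated for
#' completeness (every year x stratum cell present exactly once) and pivoted
#' to the canonical T x S matrix.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector mapping the roles `year`, `sex`,
#'   `age_group`, `value` to column names in the file. Defaults to the GBD
#'   export names `year`, `sex`, `age_name`, `val`.
#' @return An [asir_panel].
#' @export
read_panel <- function(path,
                       schema = c(year = "year", sex = "sex",
                                  age_group = "age_name", value = "val")) {
  needed <- c("year", "sex", "age_group", "value")
  if (!all(needed %in% names(schema))) {
    stop("`schema` must map year, sex, age_group and value", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(schema[needed]), names(df))
  if (length(missing_cols)) {
    stop("CSV is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  long <- data.frame(
    year = as.integer(df[[schema[["year"]]]]),
    sex = tolower(as.character(df[[schema[["sex"]]]])),
    age_group = as.character(df[[schema[["age_group"]]]]),
    value = as.numeric(df[[schema[["value"]]]]),
    stringsAsFactors = FALSE
  )
  if (any(long$value < 0, na.rm = TRUE)) {
    bad <- long[which(long$value < 0)[1L], ]
    stop(sprintf("negative rate at (%d, %s, %s)", bad$year, bad$sex,
                 bad$age_group), call. = FALSE)
  }
  years <- seq.int(min(long$year), max(long$year))  # a fully absent year is a gap
  strata <- unique(long[, c("sex", "age_group")])
  strata <- strata[canonical_stratum_order(strata), , drop = FALSE]
  rownames(strata) <- NULL
  key <- paste(long$sex, long$age_group, sep = "|")
  skey <- paste(strata$sex, strata$age_group, sep = "|")
  cell <- paste(long$year, key, sep = "@")
  if (anyDuplicated(cell)) {
    dup <- unique(cell[duplicated(cell)])
    stop("duplicate record(s): ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  expected <- as.vector(outer(years, skey, paste, sep = "@"))
  gaps <- setdiff(expected, cell)
  if (length(gaps)) {
    stop("incomplete panel; missing cell(s): ",
         paste(utils::head(gaps, 5L), collapse = ", "),
         if (length(gaps) > 5L) sprintf(" (+%d more)", length(gaps) - 5L),
         call. = FALSE)
  }
  values <- matrix(NA_real_, length(years), length(skey))
  ri <- match(long$year, years)
  ci <- match(key, skey)
  values[cbind(ri, ci)] <- long$value
  asir_panel(years, strata, values)
}

#' Write a panel as a long-format CSV
#'
#' Emits the same dialect [read_panel] consumes, in year-major, canonical
#' stratum order.
#'
#' @param panel An [asir_panel].
#' @param path Output file path.
#' @param schema Column-name map as in [read_panel].
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path,
                        schema = c(year = "year", sex = "sex",
                                   age_group = "age_name", value = "val")) {
  stopifnot(inherits(panel, "asir_panel"))
  long <- panel_to_long(panel)
  names(long) <- unname(schema[c("year", "sex", "age_group", "value")])
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Panel to long-format data frame
#' @param panel An [asir_panel].
#' @return Data frame with columns year, sex, age_group, value.
#' @export
panel_to_long <- function(panel) {
  Tn <- length(panel$years); S <- nrow(panel$strata)
  data.frame(
    year = rep(panel$years, each = S),
    sex = rep(panel$strata$sex, times = Tn),
    age_group = rep(panel$strata$age_group, times = Tn),
    value = as.vector(t(panel$values)),
    stringsAsFactors = FALSE
  )
}

# Population standard deviation (divide by n); fixed so normalization tests
# are exact.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-stratum z-normalization
#'
#' Standardizes each stratum series to zero mean and unit (population)
#' standard deviation, with the statistics fitted on `fit_years` only. Fitting
#' per stratum (rather than globally) keeps the low-rate young age groups on
#' the same footing as the high-rate elderly groups, whose levels differ by
#' two orders of magnitude.
#'
#' @param panel An [asir_panel] in rate units.
#' @param fit_years Years over which the mean and SD are computed; defaults to
#'   all panel years. Must be a subset of `panel$years`.
#' @return List with `panel` (z-units, class `asir_panel_z`) and `params`
#'   (class `norm_params`: vectors `mu`, `sigma`, plus `fit_years` and the
#'   stratum table).
#' @export
normalize_panel <- function(panel, fit_years = panel$years) {
  stopifnot(inherits(panel, "asir_panel") || inherits(panel, "asir_panel_z"))
  fit_years <- as.integer(fit_years)
  if (!all(fit_years %in% panel$years)) {
    stop("`fit_years` must be a subset of panel years", call. = FALSE)
  }
  idx <- match(fit_years, panel$years)
  sub <- panel$values[idx, , drop = FALSE]
  mu <- colMeans(sub)
  sigma <- apply(sub, 2L, sd_pop)
  if (any(sigma <= 0)) {
    bad <- stratum_labels(panel)[sigma <= 0]
    stop("zero variance over fit years in stratum: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(panel$values, 2L, mu, "-"), 2L, sigma, "/")
  zp <- structure(list(years = panel$years, strata = panel$strata, values = z),
                  class = c("asir_panel_z"))
  colnames(zp$values) <- colnames(panel$values)
  rownames(zp$values) <- rownames(panel$values)
  params <- structure(
    list(mu = mu, sigma = sigma, fit_years = fit_years,
         strata = panel$strata),
    class = "norm_params"
  )
  list(panel = zp, params = params)
}

#' Invert a z-normalization
#'
#' @param panel_z Panel in z-units (as returned by [normalize_panel]).
#' @param params A `norm_params` object whose strata match the panel's.
#' @return An [asir_panel] in rate units.
#' @export
denormalize_panel <- function(panel_z, params) {
  stopifnot(inherits(params, "norm_params"))
  if (!identical(paste(panel_z$strata$sex, panel_z$strata$age_group),
                 paste(params$strata$sex, params$strata$age_group))) {
    stop("normalization params strata do not match panel strata", call. = FALSE)
  }
  x <- sweep(sweep(panel_z$values, 2L, params$sigma, "*"), 2L, params$mu, "+")
  # clamp tiny negative round-off so the rate-unit invariant holds
  x[x < 0 & x > -1e-9] <- 0
  asir_panel(panel_z$years, panel_z$strata, x)
}

# z-matrix helper used internally where full panel objects are not needed
apply_norm <- function(values, params) {
  sweep(sweep(values, 2L, params$mu, "-"), 2L, params$sigma, "/")
}
invert_norm <- function(zvalues, params) {
  sweep(sweep(zvalues, 2L, params$sigma, "*"), 2L, params$mu, "+")
}
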