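#' Cut sliding-window samples from a panel
#'
#' Every anchor year t with a full w-year history and h-year future yields one
#' multivariate sample: input = rows `[t-w+1, t]` (w x S), target = rows
#' `[t+1, t+h]` (h x S). A length-T panel yields `N = T - w - h + 1` windows,
#' returned in chronological anchor order. Values are copies of the panel
#' rows; mutating the dataset does not touch the panel.
#'
#' @param panel An `asir_panel` or `asir_panel_z` (training uses z-units).
#' @param w Window (history) length in years; default 10.
#' @param h Forecast horizon in years; default 5.
#' @return A `windowed_dataset`: `inputs` (N x w x S array), `targets`
#'   (N x h x S array), `anchor_years` (length N), `w`, `h`, `strata`.
#' @export
make_windows <- function(panel, w = 10L, h = 5L) {
  w <- as.integer(w); h <- as.integer(h)
  stopifnot(w >= 1L, h >= 1L)
  Tn <- length(panel$years); S <- ncol(panel$values)
  if (Tn < w + h) {
    stop(sprintf("series too short: T = %d but w + h = %d years are required",
                 Tn, w + h), call. = FALSE)
  }
  n <- Tn - w - h + 1L
  inputs <- array(0, c(n, w, S))
  targets <- array(0, c(n, h, S))
  anchors <- integer(n)
  for (k in seq_len(n)) {
    t_idx <- w + k - 1L                       # index of anchor year
    inputs[k, , ] <- panel$values[(t_idx - w + 1L):t_idx, , drop = FALSE]
    targets[k, , ] <- panel$values[(t_idx + 1L):(t_idx + h), , drop = FALSE]
    anchors[k] <- panel$years[t_idx]
  }
  structure(list(inputs = inputs, targets = targets, anchor_years = anchors,
                 w = w, h = h, strata = panel$strata),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows (w = %d, h = %d, S = %d)\n",
              dim(x$inputs)[1L], x$w, x$h, dim(x$inputs)[3L]))
  invisible(x)
}

#' Count sliding-window samples
#'
#' `windows` is the number of multivariate windows, `T - w - h + 1`.
#' `paper_style` multiplies by the number of strata S — the per-subsequence
#' counting convention under which the canonical 32-year, 24-stratum panel
#' yields 432 samples even though training consumes 18 multivariate windows.
#'
#' @param T_years Panel length in years.
#' @param S Number of strata.
#' @param w,h Window and horizon lengths.
#' @return List with `windows` and `paper_style`.
#' @export
count_samples <- function(T_years, S, w = 10L, h = 5L) {
  T_years <- as.integer(T_years); S <- as.integer(S)
  w <- as.integer(w); h <- as.integer(h)
  if (T_years < w + h) {
    stop(sprintf("series too short: T = %d but w + h = %d years are required",
                 T_years, w + h), call. = FALSE)
  }
  n <- T_years - w - h + 1L
  list(windows = n, paper_style = n * S)
}

# Subset a windowed dataset by window index (used for seeded shuffling and
# fold assembly).
subset_windows <- function(ds, idx) {
  structure(list(inputs = ds$inputs[idx, , , drop = FALSE],
                 targets = ds$targets[idx, , , drop = FALSE],
                 anchor_years = ds$anchor_years[idx],
                 w = ds$w, h = ds$h, strata = ds$strata),
            class = "windowed_dataset")
}
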