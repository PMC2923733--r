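# Time grid and sampled conductance series containers.
#
# Conventions used package-wide: time is in seconds from recording start,
# sample indices are 0-based in the time mapping (sample k sits at
# t0 + k/rate), and all windows are half-open [start, end).

#' Create a uniform sampling grid
#'
#' @param rate Sampling rate in Hz (positive).
#' @param n Number of samples.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `time_grid`.
#' @examples
#' g <- time_grid(10, 100)
#' head(grid_times(g))
#' @export
time_grid <- function(rate, n, t0 = 0) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a positive number (Hz)")
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("`n` must be a non-negative integer")
  structure(list(rate = rate, n = n, t0 = t0), class = "time_grid")
}

#' Sample times of a grid
#'
#' @param grid A `time_grid`.
#' @return Numeric vector of length `grid$n`: `t0 + k/rate`, k = 0, 1, ...
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + (seq_len(grid$n) - 1) / grid$rate
}

#' Map a time in seconds to the nearest-not-after sample index
#'
#' Half-open window convention: `grid_index(g, t)` is the 1-based index of
#' the first sample at or after `t`.
#' @param grid A `time_grid`.
#' @param t Time(s) in seconds.
#' @return Integer indices (1-based, may fall outside `[1, n]`).
#' @export
grid_index <- function(grid, t) {
  as.integer(ceiling((t - grid$t0) * grid$rate - 1e-9)) + 1L
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: %d samples at %g Hz, t0 = %g s (%.1f s)\n",
              x$n, x$rate, x$t0, x$n / x$rate))
  invisible(x)
}

#' Create a sampled skin conductance series
#'
#' @param grid A `time_grid`.
#' @param values Numeric vector of conductance values, one per sample.
#' @param units One of `"microsiemens"`, `"z-units"`, `"arbitrary"`.
#' @return An object of class `sc_timeseries`.
#' @export
sc_timeseries <- function(grid, values,
                          units = c("microsiemens", "z-units", "arbitrary")) {
  stopifnot(inherits(grid, "time_grid"))
  units <- match.arg(units)
  values <- as.numeric(values)
  if (length(values) != grid$n)
    stop("length(values) must equal grid$n")
  if (any(!is.finite(values)))
    stop("conductance values must be finite")
  structure(list(grid = grid, values = values, units = units),
            class = "sc_timeseries")
}

#' @export
print.sc_timeseries <- function(x, ...) {
  cat(sprintf("sc_timeseries: %d samples at %g Hz (%s), range [%.3g, %.3g]\n",
              x$grid$n, x$grid$rate, x$units,
              min(x$values), max(x$values)))
  invisible(x)
}
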