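# Signal conditioning: zero-phase first-order Butterworth band-pass,
# decimation, whole-series z-transform.
#
# The band-pass is implemented as a cascade of a first-order high-pass
# (cut-off 1/(2*pi*time_constant), i.e. 0.0159 Hz for the default 10 s
# time constant) and a first-order low-pass (default 5 Hz), each realised
# by bilinear transform. "Bidirectional" means forward-backward filtering
# (zero phase; the magnitude response of the single pass is squared).

#' Preprocessing configuration
#'
#' @param high_cutoff Low-pass corner frequency in Hz (default 5).
#' @param time_constant High-pass time constant in seconds (default 10);
#'   the corner frequency is `1/(2*pi*time_constant)`.
#' @param target_rate Output sampling rate in Hz (default 10).
#' @param filter_order Order per edge (only 1 supported).
#' @param bidirectional Forward-backward (zero-phase) filtering, default TRUE.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(high_cutoff = 5, time_constant = 10,
                              target_rate = 10, filter_order = 1L,
                              bidirectional = TRUE) {
  if (filter_order != 1L) stop("only first-order sections are supported")
  low_cutoff <- 1 / (2 * pi * time_constant)
  if (!(low_cutoff > 0 && low_cutoff < high_cutoff))
    stop("need 0 < low cutoff < high_cutoff")
  structure(list(high_cutoff = high_cutoff, time_constant = time_constant,
                 low_cutoff = low_cutoff, target_rate = target_rate,
                 filter_order = 1L, bidirectional = isTRUE(bidirectional)),
            class = "preprocess_config")
}

# One first-order IIR pass, y[i] = b0 x[i] + b1 x[i-1] - a1 y[i-1],
# vectorised through stats::filter.
iir1 <- function(x, b, a1) {
  xf <- b[1] * x + b[2] * c(x[1], x[-length(x)])
  as.numeric(stats::filter(xf, -a1, method = "recursive"))
}

# First-order Butterworth coefficients by bilinear transform with
# frequency prewarping; fc in Hz, fs in Hz.
butter1 <- function(fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  c0 <- tan(pi * fc / fs)
  if (type == "low") list(b = c(c0, c0) / (1 + c0), a1 = (c0 - 1) / (1 + c0))
  else list(b = c(1, -1) / (1 + c0), a1 = (c0 - 1) / (1 + c0))
}

# Apply one section forward (and backward if bidirectional), with
# reflect-padding of `pad` samples to absorb edge transients.
apply_section <- function(x, coef, bidirectional, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- if (pad > 0)
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  else x
  y <- iir1(xp, coef$b, coef$a1)
  if (bidirectional) y <- rev(iir1(rev(y), coef$b, coef$a1))
  y[(pad + 1):(pad + n)]
}

#' Band-pass filter a conductance series
#'
#' @param series An `sc_timeseries`.
#' @param cfg A `preprocess_config`.
#' @return Filtered `sc_timeseries` (same grid and units).
#' @export
bandpass <- function(series, cfg = preprocess_config()) {
  stopifnot(inherits(series, "sc_timeseries"),
            inherits(cfg, "preprocess_config"))
  fs <- series$grid$rate
  if (cfg$high_cutoff >= fs / 2)
    stop("high_cutoff must be below the Nyquist frequency")
  pad <- as.integer(3 * cfg$time_constant * fs)
  y <- series$values
  y <- apply_section(y, butter1(cfg$low_cutoff, fs, "high"),
                     cfg$bidirectional, pad)
  y <- apply_section(y, butter1(cfg$high_cutoff, fs, "low"),
                     cfg$bidirectional, pad)
  sc_timeseries(series$grid, y, units = series$units)
}

#' Downsample by integer decimation
#'
#' Keeps every `rate/target_rate`-th sample starting from the first; call
#' after [bandpass()], which already suppresses the relevant high
#' frequencies.
#'
#' @param series An `sc_timeseries`.
#' @param target_rate Target rate in Hz; the input rate must be an integer
#'   multiple of it.
#' @return Decimated `sc_timeseries`.
#' @export
downsample <- function(series, target_rate) {
  stopifnot(inherits(series, "sc_timeseries"))
  fs <- series$grid$rate
  ratio <- fs / target_rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("input rate must be an integer multiple of target_rate")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(series)
  idx <- seq(1L, series$grid$n, by = ratio)
  sc_timeseries(time_grid(target_rate, length(idx), series$grid$t0),
                series$values[idx], units = series$units)
}

#' Z-transform a whole series
#'
#' Centres and scales the entire series to mean 0, SD 1 (sample SD, n - 1
#' denominator), flagging the units as z-units. Accounts for
#' between-subject differences in overall responsiveness.
#'
#' @param series An `sc_timeseries`.
#' @return `sc_timeseries` in z-units.
#' @export
ztransform <- function(series) {
  stopifnot(inherits(series, "sc_timeseries"))
  s <- stats::sd(series$values)
  if (!is.finite(s) || s <= 0)
    stop("cannot z-transform a zero-variance series")
  sc_timeseries(series$grid, (series$values - mean(series$values)) / s,
                units = "z-units")
}

#' Run the full preprocessing pipeline
#'
#' Enforces the canonical stage order band-pass -> downsample ->
#' z-transform.
#'
#' @param series An `sc_timeseries`.
#' @param cfg A `preprocess_config`.
#' @param ztrans Apply the final z-transform (default TRUE).
#' @return Preprocessed `sc_timeseries`.
#' @export
preprocess <- function(series, cfg = preprocess_config(), ztrans = TRUE) {
  out <- downsample(bandpass(series, cfg), cfg$target_rate)
  if (ztrans) out <- ztransform(out)
  out
}
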