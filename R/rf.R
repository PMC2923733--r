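# Response functions: causal impulse-response kernels mapping sudomotor
# input to conductance, and the convolution / integration operators.
#
# The phasic kernel family is a Gaussian-smoothed biexponential,
#   g(t) = [exp(-t/tau1) - exp(-t/tau2)] (*) N(0, sigma_g^2),  t >= 0,
# with tau1 > tau2 (decay and rise time constants, s) and smoothing SD
# sigma_g (s). Kernels are normalised so that convolving a reference bump
# of unit amplitude and 0.3 s dispersion gives a peak of exactly 1; this
# defines the "sudomotor unit": a burst of one unit produces a 1 uS (or
# 1 z-unit) peak deflection.

REF_BUMP_DISPERSION <- 0.3

default_rf_shape <- function(kind) {
  switch(kind,
         scr = c(tau1 = 3.5, tau2 = 0.75, sigma_g = 0.5),
         sf  = c(tau1 = 2.0, tau2 = 0.50, sigma_g = 0.3),
         stop("unknown RF kind"))
}

#' Build a canonical response function
#'
#' @param kind `"scr"` (anticipatory/evoked responses) or `"sf"`
#'   (spontaneous fluctuations); the two default shapes differ in recovery
#'   speed, the SCR kernel being slower.
#' @param shape_params Named or positional numeric vector
#'   `(tau1, tau2, sigma_g)` in seconds; defaults depend on `kind`.
#' @param rate Sampling rate of the cached kernel (Hz, default 10).
#' @param support Kernel length in seconds (default 30). The kernel must
#'   have decayed below 1e-3 of its peak by the end of the support.
#' @return An object of class `response_function` with elements `kind`,
#'   `shape`, `rate`, `support`, `kernel` (sampled, unit-normalised) and
#'   `norm` (the raw-kernel peak response divided out).
#' @export
canonical_rf <- function(kind = c("scr", "sf"), shape_params = NULL,
                         rate = 10, support = 30) {
  kind <- match.arg(kind)
  p <- if (is.null(shape_params)) default_rf_shape(kind) else shape_params
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)) || any(p <= 0))
    stop("shape_params must be three positive numbers (tau1, tau2, sigma_g)")
  tau1 <- p[1]; tau2 <- p[2]; sg <- p[3]
  if (tau1 <= tau2)
    stop("tau1 (decay) must exceed tau2 (rise)")
  k <- rf_kernel_raw(tau1, tau2, sg, rate, support)
  nk <- length(k)
  tail_max <- max(abs(k[(nk - rate + 1):nk]))
  if (tail_max >= 1e-3 * max(k))
    stop("kernel has not decayed below 1e-3 of its peak within the support; ",
         "increase `support` or reduce tau1")
  rf <- structure(list(kind = kind,
                       shape = c(tau1 = tau1, tau2 = tau2, sigma_g = sg),
                       rate = rate, support = support,
                       kernel = k, norm = 1),
                  class = "response_function")
  # unit-peak normalisation against the reference bump
  peak <- ref_bump_peak(rf)
  rf$kernel <- rf$kernel / peak
  rf$norm <- peak
  rf
}

# Raw (unnormalised) kernel: causal biexponential smoothed by a Gaussian
# window, truncated to t >= 0 with k(0) = 0 enforced (causality).
rf_kernel_raw <- function(tau1, tau2, sg, rate, support) {
  dt <- 1 / rate
  t <- seq(0, support - dt, by = dt)
  g <- exp(-t / tau1) - exp(-t / tau2)
  m <- max(3L, as.integer(ceiling(4 * sg * rate)))
  tw <- (-m:m) * dt
  w <- exp(-tw^2 / (2 * sg^2))
  w <- w / sum(w)
  full <- conv_full(g, w)
  k <- full[(m + 1):(m + length(t))]  # zero-phase alignment
  k[1] <- 0
  pmax(k, 0)
}

# peak response of the unit reference bump under this (current) kernel
ref_bump_peak <- function(rf) {
  g <- time_grid(rf$rate, as.integer((rf$support + 10) * rf$rate))
  x <- bump_timecourse(1, 5 * REF_BUMP_DISPERSION, REF_BUMP_DISPERSION, g)
  max(conv_causal(x, rf$kernel))
}

#' @export
print.response_function <- function(x, ...) {
  pk <- which.max(x$kernel)
  cat(sprintf(
    "response_function (%s): tau1=%.3g tau2=%.3g sigma_g=%.3g s, %g Hz, %g s support, peak lag %.2f s\n",
    x$kind, x$shape[1], x$shape[2], x$shape[3], x$rate, x$support,
    (pk - 1) / x$rate))
  invisible(x)
}

# Full linear convolution (length nx + nk - 1), FFT for long inputs.
conv_full <- function(x, k) {
  nx <- length(x); nk <- length(k)
  if (as.double(nx) * nk <= 2e4) {
    # direct convolution via filtering keeps small problems allocation-light
    out <- numeric(nx + nk - 1)
    for (j in seq_len(nk)) {
      if (k[j] != 0) out[j:(j + nx - 1)] <- out[j:(j + nx - 1)] + k[j] * x
    }
    out
  } else {
    L <- stats::nextn(nx + nk - 1, 2)
    xp <- c(x, numeric(L - nx)); kp <- c(k, numeric(L - nk))
    out <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / L
    out[seq_len(nx + nk - 1)]
  }
}

# Causal convolution truncated to the input length: out[k] depends only on
# x[1..k] (discrete sum; multiply by dt for the continuous-time integral).
conv_causal <- function(x, k) {
  conv_full(x, k)[seq_along(x)]
}

#' Convolve a sampled input with a response function
#'
#' Causal discrete convolution `sum_j x[j] k[i - j + 1]`, truncated to the
#' input length, so a unit impulse returns the kernel samples. The
#' sudomotor-unit normalisation of [canonical_rf()] is defined under this
#' convention.
#'
#' @param signal Numeric vector sampled at `rate`, or an `sc_timeseries`.
#' @param rf A `response_function` with matching sampling rate.
#' @param rate Sampling rate of `signal` when given as a bare vector.
#' @return Numeric vector of the same length as the input.
#' @export
convolve_rf <- function(signal, rf, rate = NULL) {
  stopifnot(inherits(rf, "response_function"))
  if (inherits(signal, "sc_timeseries")) {
    rate <- signal$grid$rate
    signal <- signal$values
  }
  if (is.null(rate)) stop("supply `rate` for a bare numeric signal")
  if (abs(rate - rf$rate) > 1e-9)
    stop("signal and response function sampling rates differ")
  conv_causal(signal, rf$kernel)
}

#' Accumulate (integrate) an input signal
#'
#' The SCL drift component uses an integrating response: the output is the
#' running time-integral of the input, so a Gaussian drift bump becomes a
#' smooth step.
#'
#' @param signal Numeric vector or `sc_timeseries`.
#' @param grid A `time_grid` (ignored when `signal` is an `sc_timeseries`).
#' @return Numeric vector: `cumsum(signal) / rate`.
#' @export
integrate_scl <- function(signal, grid = NULL) {
  if (inherits(signal, "sc_timeseries")) {
    grid <- signal$grid
    signal <- signal$values
  }
  stopifnot(inherits(grid, "time_grid"))
  cumsum(signal) / grid$rate
}
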