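# Data-driven estimation of the SCR response function: evoked responses
# (US and US omission) are epoch-extracted, summarised by their first
# principal component, and the canonical kernel family plus an
# event-to-response latency is least-squares fitted to that component.

#' Extract event-locked epochs
#'
#' @param series An `sc_timeseries` (typically preprocessed).
#' @param onsets Event onsets in seconds, sorted.
#' @param window Two-element numeric `[start, end)` in seconds relative to
#'   each onset (default `c(0, 20)`).
#' @return An object of class `epoch_matrix`: matrix (one row per retained
#'   event) with attributes `window`, `rate`, `onsets` and `n_dropped`
#'   (events whose window exceeded the recording).
#' @export
extract_epochs <- function(series, onsets, window = c(0, 20)) {
  stopifnot(inherits(series, "sc_timeseries"), length(window) == 2L,
            window[2] > window[1])
  if (is.unsorted(onsets)) stop("`onsets` must be sorted")
  g <- series$grid
  len <- as.integer(round((window[2] - window[1]) * g$rate))
  starts <- grid_index(g, onsets + window[1])
  keep <- starts >= 1L & (starts + len - 1L) <= g$n
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no epoch fits inside the recording")
  rows <- lapply(starts[keep], function(s) series$values[s:(s + len - 1L)])
  m <- do.call(rbind, rows)
  structure(m, class = c("epoch_matrix", class(m)),
            window = window, rate = g$rate,
            onsets = onsets[keep], n_dropped = n_dropped)
}

#' First principal component of an epoch matrix
#'
#' Columns (time points) are mean-centred; the first eigenvector of the
#' resulting covariance summarises the common response shape. The sign is
#' fixed so the largest-magnitude element is positive.
#'
#' @param epochs An `epoch_matrix` (or plain matrix) with >= 2 rows.
#' @return List with `component` (unit-norm vector, one element per time
#'   point), `explained` (fraction of variance), `mean` (column means) and
#'   `centred` (FALSE when identical rows forced the uncentred
#'   cross-product fallback).
#' @export
first_pc <- function(epochs) {
  m <- unclass(epochs)
  if (!is.matrix(m) || nrow(m) < 2L) stop("need at least 2 epochs")
  mc <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(mc, nu = 0, nv = 1)
  centred <- TRUE
  if (sv$d[1] <= 1e-12 * max(abs(m), 1)) {
    # identical rows: the centred matrix is null; fall back to the
    # uncentred cross-product, whose PC1 is the common shape
    if (all(m == 0)) stop("epoch matrix is rank 0")
    sv <- svd(m, nu = 0, nv = 1)
    centred <- FALSE
  }
  v <- sv$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  list(component = v,
       explained = sv$d[1]^2 / sum(sv$d^2),
       mean = colMeans(m), centred = centred)
}

# Sampled model for fit_rf: scale * kernel(tau1, tau2, sg) delayed by `lat`
# seconds, on the epoch grid. Delay is applied by sub-sample shifting of
# the continuous kernel formula, so latency is not quantised to samples.
rf_fit_model <- function(par, n, rate) {
  tau1 <- exp(par[1]); tau2 <- exp(par[2]); sg <- exp(par[3])
  lat <- par[4]; scl <- par[5]
  t <- (seq_len(n) - 1) / rate - lat
  g <- ifelse(t > 0, exp(-t / tau1) - exp(-t / tau2), 0)
  m <- max(3L, as.integer(ceiling(4 * sg * rate)))
  w <- exp(-((-m:m) / rate)^2 / (2 * sg^2)); w <- w / sum(w)
  k <- conv_full(g, w)[(m + 1):(m + n)]
  scl * pmax(k, 0)
}

#' Fit the canonical kernel family to a principal component
#'
#' Least-squares fit of shape parameters, a latency shift and a free scale
#' to the PC1 waveform, with seeded multi-start over log-spaced time
#' constants (the biexponential error surface is multimodal). The returned
#' kernel is re-normalised to the sudomotor-unit convention; the latency is
#' returned separately and is used as the fixed evoked-response delay
#' during inversion.
#'
#' @param pc Numeric vector (PC1) sampled at `rate`, or the list returned
#'   by [first_pc()].
#' @param rate Sampling rate in Hz (default 10).
#' @param family Kernel family; only `"scr"` is supported.
#' @param support Kernel support in seconds for the returned RF.
#' @param n_starts Number of multi-start initialisations (default 8).
#' @param seed Integer seed for the start jitter.
#' @return List with `rf` (a unit-normalised `response_function`), `latency`
#'   (s), `scale`, `rss` and `converged`.
#' @export
fit_rf <- function(pc, rate = 10, family = "scr", support = 30,
                   n_starts = 8, seed = 1) {
  if (is.list(pc)) pc <- pc$component
  if (family != "scr") stop("only the 'scr' family is supported")
  n <- length(pc)
  if (n < 5 * rate) stop("principal component too short to constrain the kernel")
  # responses lag their event by a couple of seconds at most; initialise
  # (and bound) the latency from the early part of the window so that a
  # following trial's response inside a long epoch cannot capture the fit
  peak_idx <- which.max(pc[seq_len(min(length(pc), as.integer(8 * rate)))])
  # latency and rise shape trade off almost freely in this family, so the
  # shape parameters are mildly regularised towards the canonical kernel;
  # the penalty scales with ||pc||^2, keeping the fit scale-invariant
  shape0 <- log(default_rf_shape("scr"))
  w_pen <- 0.02 * sum(pc^2)
  obj <- function(par) {
    if (par[1] <= par[2]) return(1e6 * (1 + par[2] - par[1]))
    r <- pc - rf_fit_model(par, n, rate)
    sum(r^2) + w_pen * sum((par[1:3] - shape0)^2)
  }
  set.seed(seed)
  tau1_grid <- exp(seq(log(1.5), log(8), length.out = n_starts))
  best <- NULL
  for (i in seq_len(n_starts)) {
    lat0 <- max(0, (peak_idx - 1) / rate - 2) * stats::runif(1, 0.5, 1)
    p0 <- c(log(tau1_grid[i]), log(tau1_grid[i] / 4), log(0.4), lat0,
            max(pc) / 0.5)
    fit <- try(stats::optim(p0, obj, method = "L-BFGS-B",
                            lower = c(log(0.3), log(0.05), log(0.05), -2, 1e-6),
                            upper = c(log(15), log(10), log(1.2), 5, Inf),
                            control = list(maxit = 400)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("RF fit failed to converge from any start")
  p <- best$par
  # grow the support if a slow fitted decay needs it to reach the <1e-3 tail
  tau1 <- exp(p[1]); tau2 <- exp(p[2])
  tpk <- log(tau1 / tau2) * tau1 * tau2 / (tau1 - tau2)
  pk <- exp(-tpk / tau1) - exp(-tpk / tau2)
  support <- max(support, ceiling(1.2 * tau1 * log(2e3 / pk)))
  rf <- canonical_rf("scr", shape_params = exp(p[1:3]), rate = rate,
                     support = support)
  list(rf = rf, latency = p[4], scale = p[5], rss = best$value,
       converged = best$convergence == 0)
}
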