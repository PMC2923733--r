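# Parameterised sudomotor nerve activity: Gaussian bump input functions.
#
# Sudomotor bursts are modelled as Gaussian bumps a * exp(-(t - mu)^2 /
# (2 sigma^2)) with amplitude a (sudomotor units), centre mu (s) and
# dispersion sigma (s). Four input classes are distinguished by where the
# design allows them: anticipatory (aSCR, inside the CS-US window), evoked
# (eSCR, at a fixed latency after the US), spontaneous fluctuations (SF,
# inter-trial intervals, rate-capped at 0.5/s) and baseline drifts (SCL,
# inter-trial intervals, the only class with signed amplitudes).

#' Construct a table of Gaussian bumps
#'
#' @param amplitude Amplitudes in sudomotor units (recycled).
#' @param center Bump centres in seconds.
#' @param dispersion Bump SDs in seconds (must be > 0).
#' @return A data.frame with columns `amplitude`, `center`, `dispersion`.
#' @export
bumps <- function(amplitude = numeric(), center = numeric(),
                  dispersion = numeric()) {
  d <- data.frame(amplitude = as.numeric(amplitude),
                  center = as.numeric(center),
                  dispersion = as.numeric(dispersion))
  if (nrow(d) > 0 && any(d$dispersion <= 0))
    stop("bump dispersion must be > 0")
  d
}

empty_bumps <- function() bumps()

#' Bundle per-class bump tables into a neural input set
#'
#' @param ascr,escr,sf,scl Bump tables (see [bumps()]); default empty.
#' @return An object of class `neural_input_set`.
#' @export
neural_inputs <- function(ascr = empty_bumps(), escr = empty_bumps(),
                          sf = empty_bumps(), scl = empty_bumps()) {
  for (b in list(ascr, escr, sf, scl)) {
    stopifnot(is.data.frame(b),
              all(c("amplitude", "center", "dispersion") %in% names(b)))
    if (nrow(b) > 0 && any(b$dispersion <= 0))
      stop("bump dispersion must be > 0")
  }
  # amplitudes are non-negative for all classes except SCL (signed drifts)
  for (nm in c("ascr", "escr", "sf")) {
    b <- get(nm)
    if (nrow(b) > 0 && any(b$amplitude < 0))
      stop(sprintf("%s amplitudes must be >= 0", nm))
  }
  structure(list(ascr = ascr, escr = escr, sf = sf, scl = scl),
            class = "neural_input_set")
}

#' @export
print.neural_input_set <- function(x, ...) {
  cat(sprintf("neural_input_set: %d aSCR, %d eSCR, %d SF, %d SCL bumps\n",
              nrow(x$ascr), nrow(x$escr), nrow(x$sf), nrow(x$scl)))
  invisible(x)
}

#' Sample one Gaussian bump on a grid
#'
#' @param amplitude,center,dispersion Bump parameters (dispersion > 0, s).
#' @param grid A `time_grid`.
#' @return Numeric vector of length `grid$n`.
#' @examples
#' g <- time_grid(10, 100)
#' y <- bump_timecourse(1, 5, 1, g)
#' y[51]  # value at t = 5 s is the amplitude
#' @export
bump_timecourse <- function(amplitude, center, dispersion, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.finite(dispersion) || dispersion <= 0)
    stop("`dispersion` must be > 0")
  t <- grid_times(grid)
  amplitude * exp(-(t - center)^2 / (2 * dispersion^2))
}

# Fast accumulation of many bumps into one signal; each bump only touches
# samples within +/- 6 SD of its centre.
sum_bumps <- function(bump_df, grid) {
  out <- numeric(grid$n)
  if (nrow(bump_df) == 0L) return(out)
  t0 <- grid$t0; rate <- grid$rate; n <- grid$n
  for (i in seq_len(nrow(bump_df))) {
    a <- bump_df$amplitude[i]
    if (a == 0) next
    mu <- bump_df$center[i]; s <- bump_df$dispersion[i]
    lo <- max(1L, as.integer(floor((mu - 6 * s - t0) * rate)) + 1L)
    hi <- min(n, as.integer(ceiling((mu + 6 * s - t0) * rate)) + 1L)
    if (lo > hi) next
    tt <- t0 + (lo:hi - 1) / rate
    out[lo:hi] <- out[lo:hi] + a * exp(-(tt - mu)^2 / (2 * s^2))
  }
  out
}

#' Sampled input time course of one input class
#'
#' Pointwise sum of the Gaussian bumps of the selected class.
#'
#' @param inputs A `neural_input_set`.
#' @param which One of `"ascr"`, `"escr"`, `"sf"`, `"scl"`.
#' @param grid A `time_grid`.
#' @param design Optional `trial_design`; when given, placement constraints
#'   are checked (aSCR centres inside their trial's anticipation window,
#'   SF/SCL centres outside all anticipation windows).
#' @return Numeric vector of length `grid$n`.
#' @export
component_input <- function(inputs, which = c("ascr", "escr", "sf", "scl"),
                            grid, design = NULL) {
  stopifnot(inherits(inputs, "neural_input_set"))
  which <- match.arg(which)
  if (!is.null(design)) validate_input_placement(inputs, design)
  sum_bumps(inputs[[which]], grid)
}

# Check design-derived placement constraints on a neural input set.
validate_input_placement <- function(inputs, design) {
  stopifnot(inherits(design, "trial_design"))
  anti <- anticipation_windows(design)
  in_any_window <- function(x) {
    ok <- logical(length(x))
    for (i in seq_len(nrow(anti)))
      ok <- ok | (x >= anti$start[i] & x < anti$end[i])
    ok
  }
  if (nrow(inputs$ascr) > 0 && !all(in_any_window(inputs$ascr$center)))
    stop("aSCR bump centre outside every anticipation window")
  for (nm in c("sf", "scl")) {
    b <- inputs[[nm]]
    if (nrow(b) > 0 && any(in_any_window(b$center)))
      stop(sprintf("%s bump centre falls inside an anticipation window", nm))
  }
  # SF rate cap: at most 0.5 bursts per second of inter-trial time
  if (nrow(inputs$sf) > 1) {
    cs <- sort(inputs$sf$center)
    if (any(diff(cs) < 2 - 1e-9))
      stop("SF bursts closer than 2 s violate the 0.5/s rate cap")
  }
  invisible(TRUE)
}
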