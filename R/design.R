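# Trial design container for discriminant delay conditioning sessions.

#' Construct a trial design
#'
#' One row per trial of a delay-conditioning session. The anticipation
#' window of a trial is `[cs_onset, us_onset)`; `us_onset = cs_onset + soa`
#' is defined on every trial (it is the scheduled US time, whether or not
#' the US is delivered). `iti` is the interval from (scheduled) US offset to
#' the next CS onset.
#'
#' @param cs_onset CS onset times in seconds (sorted, non-negative).
#' @param cs_type Character, `"CS-"` or `"CS+"` per trial.
#' @param soa Stimulus onset asynchrony in seconds (scalar or per trial).
#' @param reinforced Logical per trial; must be `FALSE` on all CS- trials.
#' @param iti Inter-trial interval following each trial, in seconds.
#' @param us_duration US duration in seconds (default 0.5).
#' @return A data.frame of class `trial_design` with columns `trial`,
#'   `cs_onset`, `cs_type`, `soa`, `us_onset`, `reinforced`, `iti`.
#' @export
trial_design <- function(cs_onset, cs_type, soa, reinforced, iti,
                         us_duration = 0.5) {
  n <- length(cs_onset)
  stopifnot(length(cs_type) == n, length(reinforced) == n)
  soa <- rep_len(soa, n)
  iti <- rep_len(iti, n)
  if (is.unsorted(cs_onset, strictly = TRUE))
    stop("cs_onset must be strictly increasing")
  if (!all(cs_type %in% c("CS-", "CS+")))
    stop('cs_type must be "CS-" or "CS+"')
  if (any(reinforced & cs_type == "CS-"))
    stop("CS- trials can never be reinforced (discriminant conditioning)")
  d <- data.frame(trial = seq_len(n), cs_onset = cs_onset,
                  cs_type = cs_type, soa = soa,
                  us_onset = cs_onset + soa,
                  reinforced = as.logical(reinforced), iti = iti)
  attr(d, "us_duration") <- us_duration
  class(d) <- c("trial_design", "data.frame")
  d
}

#' Per-trial condition labels
#'
#' @param design A `trial_design`.
#' @return Character vector: `"CS-"`, `"CS+US"` or `"CS+noUS"` per trial.
#' @export
condition_labels <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  ifelse(design$cs_type == "CS-", "CS-",
         ifelse(design$reinforced, "CS+US", "CS+noUS"))
}

#' Anticipation windows of a design
#'
#' @param design A `trial_design`.
#' @return data.frame with columns `trial`, `start`, `end` (half-open, s).
#' @export
anticipation_windows <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  data.frame(trial = design$trial, start = design$cs_onset,
             end = design$us_onset)
}

#' Inter-trial interval windows of a design
#'
#' The ITI window after trial i runs from the (scheduled) US offset plus a
#' guard margin to just before the next CS onset; the final window is capped
#' by the recorded ITI. A leading window before the first trial is included
#' when the first CS starts later than `margin` seconds into the recording.
#'
#' @param design A `trial_design`.
#' @param margin Guard interval in seconds kept clear after US offset and
#'   before CS onset (default 1).
#' @return data.frame with columns `after_trial` (0 for the leading window),
#'   `start`, `end`.
#' @export
iti_windows <- function(design, margin = 1) {
  stopifnot(inherits(design, "trial_design"))
  us_dur <- attr(design, "us_duration") %||% 0.5
  n <- nrow(design)
  starts <- design$us_onset + us_dur + margin
  ends <- c(design$cs_onset[-1], design$us_onset[n] + us_dur + design$iti[n]) -
    margin
  out <- data.frame(after_trial = design$trial, start = starts, end = ends)
  if (design$cs_onset[1] > 2 * margin)
    out <- rbind(data.frame(after_trial = 0, start = margin,
                            end = design$cs_onset[1] - margin), out)
  out[out$end > out$start, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total session duration implied by a design
#'
#' @param design A `trial_design`.
#' @param tail Extra recording time after the last trial's ITI (s).
#' @return Duration in seconds.
#' @export
session_duration <- function(design, tail = 5) {
  us_dur <- attr(design, "us_duration") %||% 0.5
  n <- nrow(design)
  design$us_onset[n] + us_dur + design$iti[n] + tail
}
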