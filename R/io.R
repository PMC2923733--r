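# Readers and writers for the package's plain-text interchange formats:
# trace CSV (time,conductance), events TSV (onset/duration/trial_type,
# compatible with the widespread events-file convention), RF JSON, and
# ground-truth bump tables. Plus the end-to-end pipeline runner.

#' Read a conductance trace from CSV
#'
#' Accepts either a two-column `time,conductance` file (seconds,
#' microsiemens; time stamps must be uniform) or a single `conductance`
#' column with the sampling rate supplied via `rate`.
#'
#' @param path File path.
#' @param rate Sampling rate in Hz for single-column files.
#' @param units Unit flag to attach (default `"microsiemens"`).
#' @return An `sc_timeseries`.
#' @export
read_trace <- function(path, rate = NULL, units = "microsiemens") {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path)
  if (ncol(d) >= 2L) {
    if (!all(c("time", "conductance") %in% names(d)))
      stop("expected columns 'time' and 'conductance' in ", path)
    bad <- which(!is.finite(d$time) | !is.finite(d$conductance))
    if (length(bad))
      stop("non-finite value at data row ", bad[1], " of ", path)
    if (nrow(d) < 2L) stop("need at least 2 samples")
    dt <- diff(d$time)
    if (any(dt <= 0)) stop("time stamps not strictly increasing at row ",
                           which(dt <= 0)[1] + 1L)
    if (max(abs(dt - dt[1])) > 1e-6)
      stop("non-uniform sampling (jitter above 1e-6 s) in ", path)
    rate <- 1 / mean(dt)
    # snap near-integer rates to avoid 1/dt rounding noise
    if (abs(rate - round(rate)) < 1e-6) rate <- round(rate)
    sc_timeseries(time_grid(rate, nrow(d), t0 = d$time[1]), d$conductance,
                  units = units)
  } else {
    if (is.null(rate))
      stop("single-column trace needs an explicit `rate`")
    bad <- which(!is.finite(d[[1]]))
    if (length(bad))
      stop("non-finite value at data row ", bad[1], " of ", path)
    sc_timeseries(time_grid(rate, nrow(d)), d[[1]], units = units)
  }
}

#' Write a conductance trace to CSV
#'
#' @param series An `sc_timeseries`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(series, path) {
  stopifnot(inherits(series, "sc_timeseries"))
  utils::write.csv(data.frame(time = grid_times(series$grid),
                              conductance = series$values),
                   path, row.names = FALSE)
  invisible(path)
}

EVENT_TYPES <- c("CS-", "CS+", "US")

#' Read an events table (TSV)
#'
#' Tab-separated with header; required columns `onset`, `duration`,
#' `trial_type` (one of `CS-`, `CS+`, `US`), optional `reinforced` and
#' `trial_index`.
#'
#' @param path File path.
#' @param strict Reject files with extra columns (default FALSE).
#' @return data.frame of class `events_table`, sorted check enforced.
#' @export
read_events <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(d)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  if (strict && length(setdiff(names(d),
                               c(need, "reinforced", "trial_index"))))
    stop("unexpected extra columns in strict mode")
  if (is.unsorted(d$onset)) stop("event onsets must be sorted")
  if (any(d$onset < 0) || any(d$duration < 0))
    stop("onsets and durations must be non-negative")
  bad <- setdiff(unique(d$trial_type), EVENT_TYPES)
  if (length(bad))
    stop("unknown trial_type(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(EVENT_TYPES, collapse = ", "))
  class(d) <- c("events_table", "data.frame")
  d
}

#' Write an events table (TSV)
#'
#' @param events data.frame with `onset`, `duration`, `trial_type`, ...
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Convert a trial design to an events table
#'
#' Each trial emits a CS row (duration = SOA, co-terminating with the
#' scheduled US) and, when reinforced, a US row.
#'
#' @param design A `trial_design`.
#' @return An `events_table` data.frame.
#' @export
design_to_events <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  us_dur <- attr(design, "us_duration") %||% 0.5
  ev <- rbind(
    data.frame(onset = design$cs_onset, duration = design$soa,
               trial_type = design$cs_type,
               reinforced = design$reinforced,
               trial_index = design$trial),
    if (any(design$reinforced))
      data.frame(onset = design$us_onset[design$reinforced],
                 duration = us_dur, trial_type = "US",
                 reinforced = TRUE,
                 trial_index = design$trial[design$reinforced]))
  ev <- ev[order(ev$onset), ]
  rownames(ev) <- NULL
  class(ev) <- c("events_table", "data.frame")
  ev
}

#' Reconstruct a trial design from an events table
#'
#' @param events An `events_table` (CS rows required; US rows optional and
#'   cross-checked against the `reinforced` flag).
#' @param tail Recording tail after the last trial used to infer the final
#'   ITI when absent (default 5 s).
#' @return A `trial_design`.
#' @export
events_to_design <- function(events, tail = 5) {
  cs <- events[events$trial_type %in% c("CS-", "CS+"), , drop = FALSE]
  if (nrow(cs) == 0L) stop("no CS rows in events table")
  n <- nrow(cs)
  us_rows <- events[events$trial_type == "US", , drop = FALSE]
  reinforced <- if ("reinforced" %in% names(cs)) as.logical(cs$reinforced)
  else cs$trial_index %in% us_rows$trial_index
  soa <- cs$duration
  us_dur <- if (nrow(us_rows)) us_rows$duration[1] else 0.5
  iti <- c(cs$onset[-1], cs$onset[n] + soa[n] + us_dur + tail) -
    (cs$onset + soa + us_dur)
  trial_design(cs$onset, cs$trial_type, soa, reinforced, iti,
               us_duration = us_dur)
}

#' Write / read a response function as JSON
#'
#' Stores family name, shape parameters, latency, sampling rate, support
#' and normalisation constant; the kernel itself is rebuilt on read.
#'
#' @param rf A `response_function`.
#' @param path Output path.
#' @param latency Event-to-response latency to store alongside (s).
#' @return `path` invisibly ([write_rf()]); a list with `rf` and
#'   `latency` ([read_rf()]).
#' @export
write_rf <- function(rf, path, latency = 0) {
  stopifnot(inherits(rf, "response_function"))
  jsonlite::write_json(
    list(family = "smoothed_biexponential", kind = rf$kind,
         shape_params = as.list(rf$shape), rate = rf$rate,
         support = rf$support, latency = latency, norm = rf$norm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rf
#' @export
read_rf <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rf <- canonical_rf(j$kind, shape_params = unlist(j$shape_params),
                     rate = j$rate, support = j$support)
  list(rf = rf, latency = j$latency)
}

#' Write ground-truth neural inputs as structured text
#'
#' One bump per row: class, amplitude, center, dispersion (TSV).
#'
#' @param inputs A `neural_input_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inputs <- function(inputs, path) {
  stopifnot(inherits(inputs, "neural_input_set"))
  rows <- do.call(rbind, lapply(c("ascr", "escr", "sf", "scl"), function(cl) {
    b <- inputs[[cl]]
    if (nrow(b) == 0L) return(NULL)
    cbind(class = cl, b)
  }))
  utils::write.table(rows %||% data.frame(class = character(),
                                          amplitude = numeric(),
                                          center = numeric(),
                                          dispersion = numeric()),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_inputs
#' @export
read_inputs <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  pick <- function(cl) {
    b <- d[d$class == cl, , drop = FALSE]
    bumps(b$amplitude, b$center, b$dispersion)
  }
  neural_inputs(ascr = pick("ascr"), escr = pick("escr"),
                sf = pick("sf"), scl = pick("scl"))
}

#' Run the full analysis pipeline on one recording
#'
#' preprocess -> RF estimation (PCA of US/omission epochs, kernel fit) ->
#' model inversion -> benchmark estimators (peak scoring, condition and
#' trial GLMs) -> condition summaries. All stages are deterministic given
#' `seed`.
#'
#' @param series Raw `sc_timeseries`.
#' @param design A `trial_design` (or `events_table`).
#' @param pre_cfg A `preprocess_config`.
#' @param inv_cfg An `invert_config`; its `escr_latency` is replaced by
#'   the fitted latency when `estimate_rf = TRUE`.
#' @param estimate_rf Estimate the SCR kernel from the data via PCA
#'   (default TRUE); otherwise the canonical default kernel is used.
#' @param seed Master seed.
#' @return List of class `pipeline_result`: `pre` (preprocessed trace),
#'   `rf_scr`, `rf_sf`, `rf_latency`, `inversion`, `peaks` (EIR per
#'   trial), `glm_trial` (canonical betas per trial), `glm_recon`
#'   (derivative-basis reconstructed peaks), `summary` (per-method CS-
#'   and CS+noUS means).
#' @export
run_pipeline <- function(series, design, pre_cfg = preprocess_config(),
                         inv_cfg = invert_config(), estimate_rf = TRUE,
                         seed = 1) {
  if (inherits(design, "events_table")) design <- events_to_design(design)
  stopifnot(inherits(series, "sc_timeseries"), inherits(design, "trial_design"))
  pre <- if (abs(series$grid$rate - pre_cfg$target_rate) < 1e-9 &&
               series$units != "microsiemens")
    series  # already model-space / preprocessed input
  else preprocess(series, pre_cfg)

  rf_sf <- canonical_rf("sf", rate = pre$grid$rate)
  rf_latency <- inv_cfg$escr_latency
  if (estimate_rf) {
    onsets <- design$us_onset
    # epoch window truncated at the shortest US -> next-CS gap so closely
    # spaced trials cannot leak the following response into the PCA
    nd <- nrow(design)
    gap <- if (nd > 1) min(design$cs_onset[-1] - design$us_onset[-nd]) else 20
    ep <- extract_epochs(pre, onsets, window = c(0, min(20, max(5, gap))))
    pc <- first_pc(ep)
    rf_est <- fit_rf(pc, rate = pre$grid$rate, seed = seed)
    rf_scr <- rf_est$rf
    rf_latency <- rf_est$latency
    inv_cfg$escr_latency <- rf_latency
  } else {
    rf_scr <- canonical_rf("scr", rate = pre$grid$rate)
  }

  inv <- invert(pre, design, rf_scr, rf_sf, cfg = inv_cfg, seed = seed)
  peaks <- peak_score(pre, design, mode = "EIR")

  dm_tr <- build_glm_design(design, rf_scr, pre$grid, mode = "trials",
                            basis = "canonical")
  fit_tr <- fit_glm(pre, dm_tr)
  lab <- fit_tr$labels
  glm_trial <- vapply(design$trial, function(tr) {
    i <- which(lab$trial == tr & lab$event != "US")
    fit_tr$betas[i]
  }, numeric(1))

  dm_rc <- build_glm_design(design, rf_scr, pre$grid, mode = "trials",
                            basis = "canonical+derivatives")
  glm_recon <- reconstruct_trial_peak(fit_glm(pre, dm_rc))

  amps <- trial_amplitudes(inv)
  methods <- list(dcm = amps, peak = peaks, glm_trial = glm_trial,
                  glm_recon = glm_recon)
  summary <- do.call(rbind, lapply(names(methods), function(m) {
    s <- summarize_conditions(data.frame(trial = design$trial,
                                         amplitude = methods[[m]]), design)
    data.frame(method = m, cs_minus = s[["CS-"]], cs_plus = s[["CS+noUS"]])
  }))
  structure(list(pre = pre, rf_scr = rf_scr, rf_sf = rf_sf,
                 rf_latency = rf_latency, inversion = inv, peaks = peaks,
                 glm_trial = glm_trial, glm_recon = glm_recon,
                 summary = summary, seed = seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  fitted RF latency: %.2f s; inversion R2 = %.3f\n",
              x$rf_latency, x$inversion$r2))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
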