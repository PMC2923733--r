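# Ground-truthed synthetic conditioning sessions. Emulates discriminant
# delay conditioning: a CS+ reinforced on exactly half of its trials by an
# aversive US, a CS- never reinforced, with design geometry and default
# response parameters mirroring the two reference experiments (presets
# "exp1": 64 trials, SOA 4/10/16 s, ITI 14/19/23 s; "exp2": 180 trials,
# SOA 3.5 s, ITI 7/9/11 s). Anticipatory amplitudes are drawn per subject
# or driven by a Rescorla-Wagner process; evoked responses follow each US
# at a fixed latency; spontaneous fluctuations are a rate-capped point
# process in the inter-trial intervals; SCL drift events are sparse signed
# steps.

#' Specify a synthetic conditioning experiment
#'
#' Defaults (amplitudes, SF rate and amplitude, SCL event rate, UR
#' latency) follow the plausible parameter ranges reported for model
#' inversions on z-transformed recordings of this paradigm; amplitudes
#' are in sudomotor units on the z scale.
#'
#' @param preset `"exp2"` (default), `"exp1"`, or `"custom"`.
#' @param n_trials_per_cs Trials per CS type.
#' @param soa CS-US stimulus onset asynchrony (s).
#' @param iti_choices ITI values drawn uniformly per trial (s).
#' @param reinforcement_rate Fraction of CS+ trials reinforced (exact
#'   count; default 0.5).
#' @param cr_minus_mean,cr_plus_mean Mean anticipatory amplitude per
#'   condition (units; defaults 1.02 / 1.24 as for z-scale inversions).
#' @param cr_sd Trial-to-trial SD of anticipatory amplitudes.
#' @param cr_dispersion_mean,cr_dispersion_sd Anticipatory bump SD (s).
#' @param ur_amplitude_mean,ur_amplitude_sd Evoked (US) amplitude (units;
#'   default 10.7, the z-scale value -- the US response dwarfs conditioned
#'   responses once series are z-normalised).
#' @param ur_latency US-to-response latency (s; default 1.9).
#' @param sf_rate SF rate in the ITIs (Hz; default 0.135, capped at 0.5).
#' @param sf_amplitude_mean,sf_amplitude_sd SF burst amplitude (units).
#' @param scl_rate SCL drift events per trial (default 0.14).
#' @param scl_amplitude_sd SD of signed SCL event amplitudes (units).
#' @param noise_sd Observation noise SD (default 0.1).
#' @param learning Drive aSCR amplitudes by a Rescorla-Wagner process.
#' @param alpha Learning rates, named `CS-`/`CS+` or scalar (default 0.2).
#' @param learn_a,learn_b Linear map amplitude = a + b * V (defaults 0.3,
#'   1.5).
#' @param rate Sampling rate of generated traces (Hz, default 10).
#' @param seed Default master seed for generation (default 1).
#' @return Object of class `experiment_spec`.
#' @export
experiment_spec <- function(preset = c("exp2", "exp1", "custom"),
                            n_trials_per_cs = NULL, soa = NULL,
                            iti_choices = NULL, reinforcement_rate = 0.5,
                            cr_minus_mean = 1.02, cr_plus_mean = 1.24,
                            cr_sd = 0.3,
                            cr_dispersion_mean = 1.1, cr_dispersion_sd = 0.2,
                            ur_amplitude_mean = 10.7, ur_amplitude_sd = 1.5,
                            ur_latency = 1.9,
                            sf_rate = 0.135, sf_amplitude_mean = 0.29,
                            sf_amplitude_sd = 0.05,
                            scl_rate = 0.14, scl_amplitude_sd = 0.18,
                            noise_sd = 0.1, learning = FALSE, alpha = 0.2,
                            learn_a = 0.3, learn_b = 1.5,
                            rate = 10, seed = 1) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    exp2 = list(n = 90L, soa = 3.5, iti = c(7, 9, 11)),
    exp1 = list(n = 32L, soa = 4, iti = c(14, 19, 23)),
    custom = list(n = 20L, soa = 3.5, iti = c(7, 9, 11)))
  spec <- list(
    preset = preset,
    n_trials_per_cs = as.integer(n_trials_per_cs %||% defaults$n),
    soa = soa %||% defaults$soa,
    iti_choices = iti_choices %||% defaults$iti,
    reinforcement_rate = reinforcement_rate,
    cr_minus_mean = cr_minus_mean, cr_plus_mean = cr_plus_mean,
    cr_sd = cr_sd, cr_dispersion_mean = cr_dispersion_mean,
    cr_dispersion_sd = cr_dispersion_sd,
    ur_amplitude_mean = ur_amplitude_mean,
    ur_amplitude_sd = ur_amplitude_sd, ur_latency = ur_latency,
    sf_rate = sf_rate, sf_amplitude_mean = sf_amplitude_mean,
    sf_amplitude_sd = sf_amplitude_sd,
    scl_rate = scl_rate, scl_amplitude_sd = scl_amplitude_sd,
    noise_sd = noise_sd, learning = isTRUE(learning),
    alpha = if (length(alpha) == 1L) c(`CS-` = alpha, `CS+` = alpha)
            else alpha,
    learn_a = learn_a, learn_b = learn_b, rate = rate, seed = seed)
  if (spec$sf_rate > 0.5)
    stop("sf_rate exceeds the 0.5 responses/s cap")
  n_reinf <- spec$n_trials_per_cs * spec$reinforcement_rate
  if (abs(n_reinf - round(n_reinf)) > 1e-9)
    stop("reinforcement_rate * n_trials_per_cs must be an integer")
  structure(spec, class = "experiment_spec")
}

#' Generate a randomised trial design
#'
#' Trial order is a seeded random permutation; ITIs are drawn uniformly
#' from `iti_choices`; exactly `reinforcement_rate * n_trials_per_cs` CS+
#' trials are reinforced (exact count by permutation, not coin flips).
#'
#' @param spec An `experiment_spec`.
#' @param seed Seed (defaults to `spec$seed`).
#' @return A `trial_design`.
#' @export
generate_design <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "experiment_spec"))
  set.seed(seed)
  n_cs <- spec$n_trials_per_cs
  cs_type <- sample(rep(c("CS-", "CS+"), each = n_cs))
  reinf <- logical(2 * n_cs)
  plus_idx <- which(cs_type == "CS+")
  n_reinf <- as.integer(round(n_cs * spec$reinforcement_rate))
  reinf[sample(plus_idx, n_reinf)] <- TRUE
  itis <- sample(spec$iti_choices, 2 * n_cs, replace = TRUE)
  us_dur <- 0.5
  # first CS after a lead-in long enough for a leading ITI window
  onsets <- numeric(2 * n_cs)
  onsets[1] <- 10
  if (2 * n_cs > 1)
    for (i in 2:(2 * n_cs))
      onsets[i] <- onsets[i - 1] + spec$soa + us_dur + itis[i - 1]
  trial_design(onsets, cs_type, spec$soa, reinf, itis, us_duration = us_dur)
}

# SF point process: thinned Poisson with a hard 2 s minimum spacing
# (implements the 0.5/s cap literally)
draw_sf_times <- function(win_start, win_end, rate_hz) {
  len <- win_end - win_start
  if (len <= 0 || rate_hz <= 0) return(numeric())
  # dead-time compensation: thinning with a 2 s refractory interval keeps
  # a fraction ~1/(1 + 2 lambda) of proposals, so propose at
  # lambda / (1 - 2 lambda) to realise the requested rate on long windows
  prop_rate <- rate_hz / max(1e-6, 1 - 2 * rate_hz)
  n_prop <- stats::rpois(1, prop_rate * len)
  if (n_prop == 0L) return(numeric())
  t <- sort(stats::runif(n_prop, win_start, win_end))
  keep <- numeric()
  last <- -Inf
  for (x in t) {
    if (x - last >= 2) { keep <- c(keep, x); last <- x }
  }
  keep
}

#' Generate one subject's session
#'
#' @param spec An `experiment_spec`.
#' @param design A `trial_design` (generated from `spec` when `NULL`).
#' @param seed Seed (defaults to `spec$seed`).
#' @return List of class `synthetic_subject` with elements `design`,
#'   `clean` and `noisy` (`sc_timeseries`), `inputs` (the ground-truth
#'   `neural_input_set`), `truth` (per-trial data.frame with the true
#'   anticipatory amplitude, centre, dispersion, condition, and the RW
#'   trace when learning is on) and `spec`.
#' @export
generate_subject <- function(spec, design = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (is.null(design)) design <- generate_design(spec, seed = seed)
  set.seed(seed + 1L)
  n <- nrow(design)
  cond <- condition_labels(design)

  V <- rep(NA_real_, n)
  if (spec$learning) {
    amp_true <- numeric(n)
    for (cs in c("CS-", "CS+")) {
      sel <- design$cs_type == cs
      lam <- as.numeric(design$reinforced[sel])
      V[sel] <- rw_trace(spec$alpha[[cs]], lam, V0 = 0.5)
    }
    amp_mean <- spec$learn_a + spec$learn_b * V
  } else {
    amp_mean <- ifelse(design$cs_type == "CS-", spec$cr_minus_mean,
                       spec$cr_plus_mean)
  }
  amp_true <- pmax(0, stats::rnorm(n, amp_mean, spec$cr_sd))
  disp_true <- pmin(pmax(stats::rnorm(n, spec$cr_dispersion_mean,
                                      spec$cr_dispersion_sd), 0.3),
                    design$soa / 2)
  # centre: mid-to-late anticipation window with mild jitter
  c_lo <- design$cs_onset + 0.25 * design$soa
  c_hi <- design$cs_onset + 0.85 * design$soa
  cen_true <- pmin(pmax(design$cs_onset + 0.6 * design$soa +
                          stats::rnorm(n, 0, 0.15 * design$soa), c_lo), c_hi)

  ascr <- bumps(amp_true, cen_true, disp_true)
  reinf <- which(design$reinforced)
  escr <- if (length(reinf))
    bumps(pmax(0.1, stats::rnorm(length(reinf), spec$ur_amplitude_mean,
                                 spec$ur_amplitude_sd)),
          design$us_onset[reinf] + spec$ur_latency,
          REF_BUMP_DISPERSION)
  else empty_bumps()

  itis <- iti_windows(design)
  sf_t <- unlist(lapply(seq_len(nrow(itis)), function(w)
    draw_sf_times(itis$start[w], itis$end[w], spec$sf_rate)))
  sf <- if (length(sf_t))
    bumps(pmax(0.05, stats::rnorm(length(sf_t), spec$sf_amplitude_mean,
                                  spec$sf_amplitude_sd)), sf_t, 0.3)
  else empty_bumps()

  scl_sel <- which(stats::runif(nrow(itis)) < spec$scl_rate)
  scl <- if (length(scl_sel))
    bumps(stats::rnorm(length(scl_sel), 0, spec$scl_amplitude_sd),
          (itis$start[scl_sel] + itis$end[scl_sel]) / 2, 1)
  else empty_bumps()
  inputs <- neural_inputs(ascr = ascr, escr = escr, sf = sf, scl = scl)

  grid <- time_grid(spec$rate,
                    as.integer(ceiling(session_duration(design) * spec$rate)))
  clean <- forward_model(inputs, canonical_rf("scr", rate = spec$rate),
                         canonical_rf("sf", rate = spec$rate), grid,
                         design = design)
  noisy <- simulate_observation(clean, spec$noise_sd, seed = seed + 2L)
  truth <- data.frame(trial = design$trial, condition = cond,
                      amplitude = amp_true, center = cen_true,
                      dispersion = disp_true, V = V)
  structure(list(design = design, clean = clean, noisy = noisy,
                 inputs = inputs, truth = truth, spec = spec),
            class = "synthetic_subject")
}

#' Generate a cohort of independent subjects
#'
#' Per-subject seeds are derived from the master seed so the whole cohort
#' is reproducible; the manifest records every generation parameter.
#'
#' @param spec An `experiment_spec`.
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Master seed (defaults to `spec$seed`).
#' @return List of class `synthetic_cohort`: `subjects` (list of
#'   `synthetic_subject`), `manifest` (list: spec fields, master seed,
#'   per-subject seeds).
#' @export
generate_cohort <- function(spec, n_subjects, seed = spec$seed) {
  stopifnot(inherits(spec, "experiment_spec"), n_subjects >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(2^30, n_subjects)
  subjects <- lapply(sub_seeds, function(s) generate_subject(spec, seed = s))
  manifest <- list(spec = unclass(spec), master_seed = seed,
                   subject_seeds = sub_seeds, n_subjects = n_subjects,
                   package_version = tryCatch(
                     as.character(utils::packageVersion("scrdcm")),
                     error = function(e) "0.0.0"))
  structure(list(subjects = subjects, manifest = manifest),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "synthetic_subject: %d trials (%s preset), %d SF, %d SCL events, noise SD %g\n",
    nrow(x$design), x$spec$preset, nrow(x$inputs$sf), nrow(x$inputs$scl),
    x$spec$noise_sd))
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, master seed %d\n",
              length(x$subjects), x$manifest$master_seed))
  invisible(x)
}
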