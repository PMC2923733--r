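# Shared fixtures, built in code at test time.

# small deterministic 4-trial session with known inputs
fixture_session <- function(ur_amp = 10.7, sf = NULL, scl = NULL,
                            soa = 3.5, iti = 9) {
  design <- trial_design(cs_onset = c(10, 23, 36, 49),
                         cs_type = c("CS+", "CS-", "CS+", "CS-"),
                         soa = soa,
                         reinforced = c(TRUE, FALSE, FALSE, FALSE),
                         iti = iti)
  true_amp <- c(1.2, 0.4, 0.9, 0.5)
  inputs <- neural_inputs(
    ascr = bumps(true_amp, design$cs_onset + 0.6 * soa,
                 c(1.0, 0.8, 1.2, 0.9)),
    escr = bumps(ur_amp, design$us_onset[design$reinforced] + 1.9, 0.3),
    sf = sf %||% bumps(), scl = scl %||% bumps())
  grid <- time_grid(10, as.integer(session_duration(design) * 10))
  rf_scr <- canonical_rf("scr")
  rf_sf <- canonical_rf("sf")
  list(design = design, inputs = inputs, grid = grid,
       rf_scr = rf_scr, rf_sf = rf_sf, true_amp = true_amp,
       trace = forward_model(inputs, rf_scr, rf_sf, grid, design = design))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent O(n*m) double-loop convolution oracle
conv_oracle <- function(x, k) {
  n <- length(x); m <- length(k)
  out <- numeric(n)
  for (i in seq_len(n))
    for (j in seq_len(min(i, m)))
      out[i] <- out[i] + x[i - j + 1] * k[j]
  out
}

light_cfg <- function(...) invert_config(outer_iters = 3L, restarts = 1L,
                                         maxit = 40L, ...)
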