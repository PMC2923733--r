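# Deterministic forward model: sudomotor input set -> skin conductance.

#' Generate a skin conductance trace from a neural input set
#'
#' Anticipatory and evoked inputs are summed before convolution with the
#' shared SCR response function; spontaneous-fluctuation inputs are
#' convolved with their own kernel; SCL drift inputs are cumulatively
#' integrated. The three conductance components are added to form the
#' compound trace.
#'
#' @param inputs A `neural_input_set`.
#' @param rf_scr A `response_function` of kind `"scr"`.
#' @param rf_sf A `response_function` of kind `"sf"`.
#' @param grid A `time_grid` (rates must match the kernels).
#' @param design Optional `trial_design` for placement validation.
#' @return An `sc_timeseries` in arbitrary (model) units.
#' @export
forward_model <- function(inputs, rf_scr, rf_sf, grid, design = NULL) {
  stopifnot(inherits(inputs, "neural_input_set"),
            inherits(rf_scr, "response_function"),
            inherits(rf_sf, "response_function"),
            inherits(grid, "time_grid"))
  if (rf_scr$kind != "scr" || rf_sf$kind != "sf")
    stop("rf_scr must be of kind 'scr' and rf_sf of kind 'sf'")
  if (!is.null(design)) validate_input_placement(inputs, design)
  scr_in <- sum_bumps(inputs$ascr, grid) + sum_bumps(inputs$escr, grid)
  sf_in <- sum_bumps(inputs$sf, grid)
  scl_in <- sum_bumps(inputs$scl, grid)
  v <- convolve_rf(scr_in, rf_scr, rate = grid$rate) +
    convolve_rf(sf_in, rf_sf, rate = grid$rate) +
    integrate_scl(scl_in, grid)
  sc_timeseries(grid, v, units = "arbitrary")
}

#' Add measurement noise to a clean trace
#'
#' @param clean An `sc_timeseries`.
#' @param noise_sd Standard deviation of iid zero-mean Gaussian noise
#'   (same units as the trace; must be >= 0).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return An `sc_timeseries` with the same grid and units.
#' @export
simulate_observation <- function(clean, noise_sd, seed = NULL) {
  stopifnot(inherits(clean, "sc_timeseries"))
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0")
  v <- clean$values
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  sc_timeseries(clean$grid, v, units = clean$units)
}
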