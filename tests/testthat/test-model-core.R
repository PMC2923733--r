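# Forward model: Gaussian bump inputs, response functions, convolution,
# SCL integration, observation noise.

test_that("bump_timecourse matches the Gaussian formula and its integral", {
  g <- time_grid(10, 100)
  y <- bump_timecourse(1, 5, 1, g)
  expect_equal(y[51], 1)  # value at t = 5 s is the peak amplitude
  expect_true(all(bump_timecourse(0, 5, 1, g) == 0))
  expect_error(bump_timecourse(1, 5, 0, g), "dispersion")

  # quadrature oracle: integral of a*exp(-(t-mu)^2/(2 s^2)) = a*s*sqrt(2*pi)
  gf <- time_grid(1000, 10000)
  y2 <- bump_timecourse(2, 5, 0.5, gf)
  oracle <- stats::integrate(function(t) 2 * exp(-(t - 5)^2 / (2 * 0.25)),
                             0, 10)$value
  expect_equal(sum(y2) / 1000, oracle, tolerance = 1e-6)
  expect_equal(oracle, 2 * 0.5 * sqrt(2 * pi), tolerance = 1e-6)
})

test_that("component_input sums bumps linearly and respects placement", {
  g <- time_grid(10, 200)
  empty <- neural_inputs()
  expect_true(all(component_input(empty, "ascr", g) == 0))

  one <- neural_inputs(sf = bumps(0.5, 8, 0.4))
  two <- neural_inputs(sf = bumps(c(0.5, 0.5), c(8, 8), c(0.4, 0.4)))
  expect_equal(component_input(two, "sf", g),
               2 * component_input(one, "sf", g))

  # brute-force summation oracle for three staggered bumps
  b <- bumps(c(0.4, 1.1, 0.7), c(3, 9, 14), c(0.5, 1.2, 0.8))
  tt <- grid_times(g)
  oracle <- rowSums(sapply(1:3, function(i)
    b$amplitude[i] * exp(-(tt - b$center[i])^2 / (2 * b$dispersion[i]^2))))
  expect_lt(max(abs(component_input(neural_inputs(ascr = b), "ascr", g) -
                      oracle)), 1e-7)

  # design constraints: aSCR outside its window, SF inside one
  des <- trial_design(c(10, 25), c("CS+", "CS-"), 3.5, c(TRUE, FALSE), 10)
  bad_ascr <- neural_inputs(ascr = bumps(1, 20, 1))
  expect_error(component_input(bad_ascr, "ascr", g, design = des),
               "anticipation")
  bad_sf <- neural_inputs(sf = bumps(0.3, 11, 0.3))
  expect_error(component_input(bad_sf, "sf", g, design = des),
               "anticipation")
})

test_that("convolve_rf is the causal discrete convolution", {
  rf <- canonical_rf("scr")
  n <- 400
  x <- numeric(n); x[1] <- 1
  out <- convolve_rf(x, rf, rate = 10)
  expect_equal(out[seq_along(rf$kernel)], rf$kernel)  # impulse response

  set.seed(7)
  a <- bump_timecourse(0.8, 12, 1.5, time_grid(10, n))
  b <- bump_timecourse(1.3, 25, 0.6, time_grid(10, n))
  expect_equal(convolve_rf(3 * a, rf, rate = 10),
               3 * convolve_rf(a, rf, rate = 10))          # homogeneity
  expect_equal(convolve_rf(a + b, rf, rate = 10),
               convolve_rf(a, rf, rate = 10) +
                 convolve_rf(b, rf, rate = 10))            # superposition
  # direct double-loop oracle
  expect_lt(max(abs(convolve_rf(a + b, rf, rate = 10) -
                      conv_oracle(a + b, rf$kernel))), 1e-10)
  expect_error(convolve_rf(a, rf, rate = 20), "rates differ")
})

test_that("integrate_scl accumulates the running integral", {
  g <- time_grid(10, 100)
  expect_true(all(integrate_scl(numeric(100), g) == 0))
  out <- integrate_scl(rep(2, 100), g)
  expect_equal(out[100], 2 * 10, tolerance = 2 / 10)  # c*T within one step
  # quadrature oracle for a fully contained bump
  y <- bump_timecourse(1.5, 5, 0.4, g)
  expect_equal(integrate_scl(y, g)[100], 1.5 * 0.4 * sqrt(2 * pi),
               tolerance = 1e-3)
})

test_that("forward_model composes components with global linearity", {
  fx <- fixture_session()
  expect_true(all(forward_model(neural_inputs(), fx$rf_scr, fx$rf_sf,
                                fx$grid)$values == 0))

  # scaling every amplitude scales the whole trace (SCL included)
  ni3 <- fx$inputs
  for (cl in c("ascr", "escr", "sf", "scl"))
    ni3[[cl]]$amplitude <- 3 * ni3[[cl]]$amplitude
  tr3 <- forward_model(ni3, fx$rf_scr, fx$rf_sf, fx$grid)
  expect_equal(tr3$values, 3 * fx$trace$values, tolerance = 1e-9)

  # superposition of disjoint input sets
  ni_a <- neural_inputs(ascr = fx$inputs$ascr)
  ni_b <- neural_inputs(escr = fx$inputs$escr)
  expect_equal(forward_model(ni_a, fx$rf_scr, fx$rf_sf, fx$grid)$values +
                 forward_model(ni_b, fx$rf_scr, fx$rf_sf, fx$grid)$values,
               fx$trace$values, tolerance = 1e-9)

  # causality: inputs after time T do not affect [0, T)
  cut <- 30
  ni_cut <- fx$inputs
  for (cl in c("ascr", "escr", "sf", "scl"))
    ni_cut[[cl]] <- ni_cut[[cl]][ni_cut[[cl]]$center < cut, , drop = FALSE]
  tr_cut <- forward_model(ni_cut, fx$rf_scr, fx$rf_sf, fx$grid)
  upto <- grid_index(fx$grid, cut - 8)  # beyond 6 SD of any removed bump
  expect_equal(tr_cut$values[1:upto], fx$trace$values[1:upto],
               tolerance = 1e-9)
})

test_that("a composite two-trial trace has the expected response peaks", {
  # CS at 0 and 15 s, USs at 4 and 19 s, 3 SF in the ITI, one SCL drift
  g <- time_grid(10, 350)
  ni <- neural_inputs(
    ascr = bumps(c(0.8, 0.8), c(2.5, 17.5), c(1, 1)),
    escr = bumps(c(2, 2), c(5.9, 20.9), c(0.3, 0.3)),
    sf = bumps(c(0.4, 0.4, 0.4), c(8, 10.5, 13), 0.3),
    scl = bumps(0.3, 11, 1))
  tr <- forward_model(ni, canonical_rf("scr"), canonical_rf("sf"), g)
  v <- tr$values[1:300]
  peaks <- which(diff(sign(diff(v))) == -2) + 1
  expect_gte(sum(v[peaks] > 0.1), 4)
})

test_that("unit convention: reference bump yields peak exactly 1", {
  for (kind in c("scr", "sf")) {
    rf <- canonical_rf(kind)
    g <- time_grid(10, 400)
    x <- bump_timecourse(1, 2, 0.3, g)
    expect_equal(max(convolve_rf(x, rf, rate = 10)), 1, tolerance = 1e-6)
  }
})

test_that("canonical_rf kernels are causal, non-negative and decaying", {
  rf <- canonical_rf("scr")
  expect_identical(rf$kernel[1], 0)
  expect_true(all(rf$kernel >= 0))
  expect_lt(rf$kernel[length(rf$kernel)], 1e-3 * max(rf$kernel))
  expect_error(canonical_rf("scr", c(0.5, 1, 0.3)), "tau1")
  expect_error(canonical_rf("scr", c(20, 0.75, 0.5)), "decayed")

  # peak latency against a dense independent grid-search oracle
  p <- rf$shape
  tfine <- seq(0, 30, by = 1e-3)
  biexp <- function(t) ifelse(t >= 0, exp(-t / p[1]) - exp(-t / p[2]), 0)
  sm <- sapply(seq(0, 8, by = 0.01), function(t0)
    sum(biexp(t0 - seq(-4 * p[3], 4 * p[3], by = 0.01)) *
          stats::dnorm(seq(-4 * p[3], 4 * p[3], by = 0.01), 0, p[3])))
  oracle_peak <- seq(0, 8, by = 0.01)[which.max(sm)]
  expect_equal((which.max(rf$kernel) - 1) / rf$rate, oracle_peak,
               tolerance = 0.1)
})

test_that("simulate_observation is reproducible additive Gaussian noise", {
  g <- time_grid(10, 1e5)
  clean <- sc_timeseries(g, numeric(1e5), units = "arbitrary")
  expect_identical(simulate_observation(clean, 0)$values, clean$values)
  a <- simulate_observation(clean, 0.1, seed = 11)
  b <- simulate_observation(clean, 0.1, seed = 11)
  expect_identical(a$values, b$values)
  expect_error(simulate_observation(clean, -0.1), "noise_sd")
  # law of large numbers: sample SD near 0.1
  expect_equal(stats::sd(a$values - clean$values), 0.1, tolerance = 0.05)
})
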