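# Benchmark estimators: peak scoring and convolution GLMs.

test_that("peak_score applies the windows and baseline of the method", {
  des <- trial_design(c(10, 30), c("CS+", "CS-"), 3.5, c(FALSE, FALSE), 12)
  g <- time_grid(10, 500)
  flat <- sc_timeseries(g, rep(2, 500))
  expect_equal(peak_score(flat, des, mode = "EIR"), c(0, 0))
  expect_equal(peak_score(flat, des, mode = "FIR"), c(0, 0))
  expect_equal(peak_score(flat, des, mode = "SIR"), c(0, 0))

  # SOA < 5 s extends the EIR window to CS onset + 5 s: a pulse at
  # CS+4.5 s (outside [CS, US)) is caught by EIR but not FIR/SIR
  pulse <- sc_timeseries(g, bump_timecourse(1, 14.5, 0.2, g))
  expect_gt(peak_score(pulse, des, 1, mode = "EIR"), 0.9)
  expect_lt(peak_score(pulse, des, 1, mode = "SIR"), 0.5)

  # triangular pulse oracle: height h at the window centre, zero baseline
  v <- numeric(500)
  ctr <- 118  # t = 11.7 s, inside trial 1's anticipation window
  v[(ctr - 5):(ctr + 5)] <- 0.8 * (1 - abs(-5:5) / 6)
  tri <- sc_timeseries(g, v)
  expect_equal(peak_score(tri, des, 1, mode = "EIR"), 0.8)
  # FIR/SIR: direct slicing oracle on the unextended window halves
  fir_oracle <- max(v[101:118]) - 0  # [10, 11.75)
  sir_oracle <- max(v[119:135])     # [11.75, 13.5)
  expect_equal(peak_score(tri, des, 1, mode = "FIR"), fir_oracle)
  expect_equal(peak_score(tri, des, 1, mode = "SIR"), sir_oracle)

  # translation equivariance: constant offsets cancel in the baseline
  shifted <- sc_timeseries(g, v + 5)
  for (m in c("EIR", "FIR", "SIR"))
    expect_equal(peak_score(shifted, des, mode = m),
                 peak_score(tri, des, mode = m), tolerance = 1e-12)

  des_early <- trial_design(0.2, "CS+", 3.5, FALSE, 10)
  expect_error(peak_score(flat, des_early, mode = "EIR"), "baseline")
})

test_that("build_glm_design counts columns per mode and basis", {
  des <- trial_design(seq(10, by = 13, length.out = 8),
                      rep(c("CS-", "CS+"), 4), 3.5,
                      c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
                      9)
  g <- time_grid(10, as.integer(session_duration(des) * 10))
  rf <- canonical_rf("scr")
  dm_cond <- build_glm_design(des, rf, g, mode = "conditions")
  expect_equal(ncol(dm_cond$X), 4)  # CS-, CS+noUS, CS+US, US
  expect_setequal(unique(dm_cond$labels$event),
                  c("CS-", "CS+noUS", "CS+US", "US"))

  # 8 CS events + 2 US events, canonical + 2 derivatives
  dm_tr <- build_glm_design(des, rf, g, mode = "trials",
                            basis = "canonical+derivatives")
  expect_equal(ncol(dm_tr$X), (8 + 2) * 3)
  # spec counting example: 8 events x 3 basis functions = 24 columns
  des8 <- trial_design(seq(10, by = 13, length.out = 8),
                       rep(c("CS-", "CS+"), 4), 3.5, rep(FALSE, 8), 9)
  dm8 <- build_glm_design(des8, rf, g, mode = "trials",
                          basis = "canonical+derivatives")
  expect_equal(ncol(dm8$X), 24)

  # a single stick's regressor is the kernel shifted to the onset
  des1 <- trial_design(10, "CS-", 3.5, FALSE, 20)
  g1 <- time_grid(10, 400)
  dm1 <- build_glm_design(des1, rf, g1, mode = "trials")
  i0 <- grid_index(g1, 10)
  expect_equal(dm1$X[i0:(i0 + length(rf$kernel) - 1), 1], rf$kernel)
})

test_that("fit_glm is exact OLS with the ML variance convention", {
  set.seed(20)
  X <- matrix(rnorm(500 * 6), 500, 6)
  beta <- c(1.5, -2, 0.3, 0, 4, -1)
  y <- drop(X %*% beta)
  fit <- fit_glm(y, X)
  expect_equal(unname(fit$betas), beta, tolerance = 1e-8)
  expect_equal(fit$k, 6); expect_equal(fit$n, 500)

  # normal-equations oracle on noisy data
  y2 <- y + rnorm(500, 0, 0.5)
  fit2 <- fit_glm(y2, X)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(unname(fit2$betas), drop(beta_oracle), tolerance = 1e-10)
  expect_equal(fit2$sigma_e2,
               sum((y2 - X %*% beta_oracle)^2) / 500, tolerance = 1e-12)

  # data orthogonal to all columns: betas ~ 0, sigma_e2 = data variance
  Q <- qr.Q(qr(cbind(X, rnorm(500))))
  yo <- Q[, 7] - X %*% solve(crossprod(X), crossprod(X, Q[, 7]))
  fit3 <- fit_glm(drop(yo), X)
  expect_lt(max(abs(fit3$betas)), 1e-10)
  expect_equal(fit3$sigma_e2, mean(yo^2), tolerance = 1e-10)

  expect_error(fit_glm(y, cbind(X, X[, 1])), "rank deficient")
})

test_that("trial-mode beta means equal condition-mode betas (noiseless)", {
  des <- trial_design(seq(10, by = 14, length.out = 6),
                      rep(c("CS-", "CS+"), 3), 3.5,
                      c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE), 10)
  g <- time_grid(10, as.integer(session_duration(des) * 10))
  rf <- canonical_rf("scr")
  dm_c <- build_glm_design(des, rf, g, mode = "conditions")
  beta_true <- c(`CS-` = 0.5, `CS+US` = 1.1, `CS+noUS` = 0.9, US = 2)
  y <- drop(dm_c$X %*% beta_true[dm_c$labels$event])
  fit_c <- fit_glm(y, dm_c)
  dm_t <- build_glm_design(des, rf, g, mode = "trials")
  fit_t <- fit_glm(y, dm_t)
  for (ev in names(beta_true)) {
    bc <- fit_c$betas[fit_c$labels$event == ev]
    bt <- mean(fit_t$betas[fit_t$labels$event == ev])
    expect_equal(unname(bt), unname(bc), tolerance = 1e-6)
  }
})

test_that("derivative-basis reconstruction suppresses latency bias", {
  des <- trial_design(10, "CS-", 3.5, FALSE, 30)
  g <- time_grid(10, 500)
  rf <- canonical_rf("scr")
  # response shifted 1 s later than the modelled onset
  shift <- 1
  resp <- numeric(500)
  i0 <- grid_index(g, 10 + shift)
  resp[i0:(i0 + length(rf$kernel) - 1)] <- 0.8 * rf$kernel
  true_peak <- 0.8 * max(rf$kernel)

  dm_can <- build_glm_design(des, rf, g, mode = "trials")
  fit_can <- fit_glm(resp, dm_can)
  can_est <- unname(fit_can$betas[1]) * max(rf$kernel)

  dm_der <- build_glm_design(des, rf, g, mode = "trials",
                             basis = "canonical+derivatives")
  fit_der <- fit_glm(resp, dm_der)
  recon <- reconstruct_trial_peak(fit_der, 1)

  expect_lt(abs(recon - true_peak) / true_peak, 0.05)
  expect_gt((true_peak - can_est) / true_peak, 0.10)

  # derivative betas zero -> reconstruction is the canonical beta x peak
  fit0 <- fit_der
  fit0$betas[c(2, 3)] <- 0
  expect_equal(reconstruct_trial_peak(fit0, 1),
               unname(fit0$betas[1]) * max(rf$kernel))
  fit00 <- fit_der
  fit00$betas[] <- 0
  expect_equal(reconstruct_trial_peak(fit00, 1), 0)
  expect_error(reconstruct_trial_peak(fit_can, 1), "derivative")
})
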