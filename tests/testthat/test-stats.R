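# Statistical layer: BIC, Bayes factors, condition prediction, CS main
# effect, Rescorla-Wagner fitting.

test_that("bic follows the per-sample formula", {
  expect_equal(bic(1, 0, 50), 0)
  expect_equal(bic(1, 0, 5000), 0)
  expect_equal(bic(1, 2, 100), 2 / 100 * log(100))
  expect_error(bic(0, 1, 10), "positive")
  expect_error(bic(-1, 1, 10), "positive")

  # likelihood-identity oracle: for a Gaussian GLM at the ML variance,
  # bic = -2*loglik/n + (k/n) log n  minus a model-independent constant
  set.seed(30)
  consts <- sapply(c(2, 5), function(k) {
    X <- matrix(rnorm(200 * k), 200, k)
    y <- rnorm(200)
    fit <- fit_glm(y, X)
    ll <- sum(stats::dnorm(y, fit$fitted, sqrt(fit$sigma_e2), log = TRUE))
    bic(fit) - (-2 * ll / fit$n + fit$k / fit$n * log(fit$n))
  })
  expect_equal(consts[1], consts[2], tolerance = 1e-10)
  expect_equal(consts[1], -(1 + log(2 * pi)), tolerance = 1e-10)

  # monotone in both arguments
  expect_gt(bic(2, 3, 100), bic(1, 3, 100))
  expect_gt(bic(1, 4, 100), bic(1, 3, 100))
})

test_that("log Bayes factors reduce to variance ratios at equal k", {
  f1 <- list(sigma_e2 = 0.5, k = 3, n = 100)
  f2 <- list(sigma_e2 = 0.5, k = 3, n = 100)
  expect_equal(as.numeric(log_bayes_factor(f1, f2)), 0)

  # printed interpretation: logBF 3 means exp(3) ~ 20 times more evidence
  f3 <- list(sigma_e2 = exp(3) * 0.5, k = 3, n = 100)
  lbf <- log_bayes_factor(f3, f2)
  expect_equal(as.numeric(lbf), 3, tolerance = 1e-12)
  expect_equal(round(exp(as.numeric(lbf))), 20)

  set.seed(31)
  for (i in 1:5) {
    s1 <- runif(1, 0.1, 2); s2 <- runif(1, 0.1, 2)
    out <- log_bayes_factor(list(sigma_e2 = s1, k = 4, n = 77),
                            list(sigma_e2 = s2, k = 4, n = 77))
    expect_equal(as.numeric(out), log(s1) - log(s2), tolerance = 1e-12)
    expect_true(attr(out, "equal_k"))
  }
  # unequal complexity falls back to the full BIC difference, flagged
  out <- log_bayes_factor(list(sigma_e2 = 1, k = 2, n = 100),
                          list(sigma_e2 = 1, k = 5, n = 100))
  expect_false(attr(out, "equal_k"))
  expect_equal(as.numeric(out), -3 / 100 * log(100))
})

make_measures <- function(sep, seed = 1, n_sub = 6, n_tr = 12) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_sub), function(s) {
    cond <- rep(c("CS-", "CS+noUS"), each = n_tr / 2)
    est <- ifelse(cond == "CS+noUS", sep, 0) + rnorm(n_tr, 0, 1)
    data.frame(subject = s, trial = seq_len(n_tr), condition = cond,
               method = "m", estimate = est)
  }))
}

test_that("condition_prediction_glm scores separability, not offsets", {
  good <- make_measures(3)
  bad <- good
  set.seed(2)
  bad$estimate <- sample(bad$estimate)  # permuted: uninformative
  fit_good <- condition_prediction_glm(good, "m")
  fit_bad <- condition_prediction_glm(bad, "m")
  expect_lt(fit_good$sigma_e2, fit_bad$sigma_e2)
  expect_lt(as.numeric(log_bayes_factor(fit_good, fit_bad)), 0)
  expect_equal(fit_good$k, 1 + 6)

  # per-subject offsets are absorbed by the subject columns
  off <- good
  off$estimate <- off$estimate + 10 * off$subject
  fit_off <- condition_prediction_glm(off, "m")
  expect_equal(fit_off$sigma_e2, fit_good$sigma_e2, tolerance = 1e-9)

  # CS+US rows are excluded silently; single-condition subjects error
  plus <- good[good$subject == 1 & good$condition == "CS-", ]
  plus$condition <- "CS+US"
  with_us <- rbind(good, transform(plus, trial = trial + 100))
  expect_equal(condition_prediction_glm(with_us, "m")$n, fit_good$n)
  solo <- good[!(good$subject == 1 & good$condition == "CS-"), ]
  expect_error(condition_prediction_glm(solo, "m"), "both")
})

test_that("cs_main_effect is the paired-contrast F", {
  m <- c(1, 2, 3, 4)
  eq <- cs_main_effect(m, m)
  expect_equal(eq$F, 0)

  # oracle: F = t^2 of the paired t-test
  set.seed(33)
  a <- rnorm(10); b <- a + rnorm(10, 0.5, 0.4)
  out <- cs_main_effect(a, b)
  tt <- t.test(b, a, paired = TRUE)
  expect_equal(out$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$p, tt$p.value, tolerance = 1e-10)

  degen <- cs_main_effect(c(1, 1, 1), c(1.5, 1.5, 1.5))
  expect_true(degen$degenerate)
  expect_equal(degen$F, Inf)

  # empirical power vs the analytic paired-t power (binomial CI)
  set.seed(34)
  nrep <- 400
  hits <- sum(replicate(nrep, {
    d0 <- rnorm(20, 0.22, 0.3)
    cs_main_effect(numeric(20), d0)$p < 0.05
  }))
  p_analytic <- power.t.test(n = 20, delta = 0.22, sd = 0.3,
                             type = "one.sample")$power
  ci <- p_analytic + c(-4, 4) * sqrt(p_analytic * (1 - p_analytic) / nrep)
  expect_gt(hits / nrep, ci[1])
  expect_lt(hits / nrep, ci[2])

  # between-subject SOA factor: mixed ANOVA path returns a finite F
  grp <- rep(c("4s", "10s"), each = 5)
  set.seed(35)
  out2 <- cs_main_effect(rnorm(10), rnorm(10, 0.4), group = grp)
  expect_true(is.finite(out2$F))
  expect_equal(out2$df[1], 1)
})

test_that("rw_update and rw_trace follow the error-driven rule", {
  expect_equal(rw_update(0.5, 0.5, 1), 0.75)
  expect_equal(rw_update(0.3, 0, 1), 0.3)
  expect_equal(rw_update(0.4, 0.7, 0.4), 0.4)  # lambda = V fixed point
  expect_error(rw_update(0.5, 1.5, 1), "alpha")

  # closed form under constant reinforcement:
  # post-update V after t trials = 1 - (1 - V0)(1 - alpha)^t
  alpha <- 0.3; V0 <- 0.5; nt <- 25
  tr <- rw_trace(alpha, rep(1, nt), V0)
  closed_pre <- 1 - (1 - V0) * (1 - alpha)^(seq_len(nt) - 1)
  expect_equal(tr, closed_pre, tolerance = 1e-12)
  expect_true(all(diff(tr) > 0))
  tr0 <- rw_trace(alpha, rep(0, nt), V0)
  expect_equal(tr0, V0 * (1 - alpha)^(seq_len(nt) - 1), tolerance = 1e-12)
  expect_true(all(diff(tr0) < 0))
})

test_that("fit_rw recovers learning rates from V-linear data", {
  set.seed(36)
  n_per <- 40
  lam_plus <- sample(rep(c(0, 1), each = n_per / 2))
  cs <- sample(rep(c("CS-", "CS+"), each = n_per))
  lam <- rep(0, length(cs))
  lam[cs == "CS+"] <- lam_plus
  V <- numeric(length(cs))
  V[cs == "CS+"] <- rw_trace(0.3, lam[cs == "CS+"])
  V[cs == "CS-"] <- rw_trace(0.3, lam[cs == "CS-"])
  est <- 0.2 + 1.0 * V
  fit <- fit_rw(est, lam, cs)
  expect_equal(unname(fit$alpha["CS+"]), 0.3, tolerance = 0.02)
  expect_gt(fit$r2, 0.999)
  expect_equal(fit$a, 0.2, tolerance = 0.01)
  expect_equal(fit$b, 1.0, tolerance = 0.02)

  flat <- fit_rw(rep(2, 40), rep(0:1, 20), rep(c("CS-", "CS+"), each = 20))
  expect_false(flat$identified)
  expect_equal(flat$b, 0)
  expect_equal(flat$r2, 0)

  expect_error(fit_rw(rnorm(12), rep(0, 12),
                      rep(c("CS-", "CS+"), c(8, 4))), "10 trials")
})

test_that("compare_measures obeys the Bayes-factor matrix identities", {
  m1 <- make_measures(2, seed = 5)
  m2 <- make_measures(0.2, seed = 6)
  m2$method <- "weak"
  cmp <- compare_measures(rbind(m1, m2))
  expect_equal(diag(cmp$log_bf), c(0, 0), ignore_attr = TRUE)
  expect_equal(cmp$log_bf["m", "weak"], -cmp$log_bf["weak", "m"])
  expect_lt(cmp$log_bf["m", "weak"], 0)  # stronger separation wins
})
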