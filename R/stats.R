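# Inference layer: BIC-based model comparison between response measures,
# condition-prediction GLMs, the CS main-effect test, and trial-by-trial
# Rescorla-Wagner learning fits.

#' Bayesian information criterion (per-sample form)
#'
#' `BIC = log(sigma_e2) + (k/n) log(n)`, with `sigma_e2` the
#' maximum-likelihood residual variance (SSE/n) of a Gaussian GLM, `k` the
#' number of predictors and `n` the number of data points. This per-sample
#' variant drops model-independent additive constants, so only BIC
#' differences between models fitted to the same data are meaningful.
#'
#' @param sigma_e2 Residual variance (> 0), or a `glm_fit`.
#' @param k Number of predictors (ignored if a fit is given).
#' @param n Number of data points (ignored if a fit is given).
#' @return BIC value.
#' @examples
#' bic(1, 2, 100)  # (2/100) * log(100)
#' @export
bic <- function(sigma_e2, k = NULL, n = NULL) {
  if (inherits(sigma_e2, "glm_fit")) {
    k <- sigma_e2$k; n <- sigma_e2$n; sigma_e2 <- sigma_e2$sigma_e2
  }
  if (!is.finite(sigma_e2) || sigma_e2 <= 0)
    stop("sigma_e2 must be positive")
  if (n <= 0 || k < 0) stop("need n > 0 and k >= 0")
  log(sigma_e2) + k / n * log(n)
}

#' Log Bayes factor between two GLMs
#'
#' Approximated as the BIC difference `BIC(model 1) - BIC(model 2)`; for
#' models sharing `k` and `n` this reduces to the log residual-variance
#' ratio. A positive value favours model 2 under the convention that the
#' better model has the smaller BIC; e.g. a value of 3 means model 2 is
#' `exp(3) ~ 20` times more likely.
#'
#' @param fit1,fit2 `glm_fit` objects (or lists with `sigma_e2`, `k`, `n`).
#' @return Log Bayes factor, with attribute `equal_k` saying whether the
#'   equal-complexity reduction applied.
#' @export
log_bayes_factor <- function(fit1, fit2) {
  eq <- fit1$k == fit2$k && fit1$n == fit2$n
  out <- if (eq) log(fit1$sigma_e2) - log(fit2$sigma_e2)
  else bic(fit1$sigma_e2, fit1$k, fit1$n) - bic(fit2$sigma_e2, fit2$k, fit2$n)
  attr(out, "equal_k") <- eq
  out
}

#' Assemble a tidy table of trial-wise response measures
#'
#' @param subject,trial,condition,method,estimate Equal-length vectors;
#'   `condition` must be `"CS-"`, `"CS+noUS"` or `"CS+US"`.
#' @return A validated data.frame of class `measure_table`.
#' @export
measure_table <- function(subject, trial, condition, method, estimate) {
  d <- data.frame(subject = subject, trial = trial, condition = condition,
                  method = method, estimate = as.numeric(estimate))
  if (!all(d$condition %in% c("CS-", "CS+noUS", "CS+US")))
    stop('condition must be "CS-", "CS+noUS" or "CS+US"')
  if (anyDuplicated(d[, c("subject", "trial", "method")]))
    stop("duplicate (subject, trial, method) rows")
  class(d) <- c("measure_table", "data.frame")
  d
}

#' Condition-prediction GLM for one response measure
#'
#' How well does a trial-wise response measure predict the condition it
#' was recorded under? The predicted variable is the CS+/CS- contrast
#' (+1 for CS+ trials not followed by a US, -1 for CS-; reinforced CS+
#' trials are excluded), the predictors are the measure's estimates plus
#' one indicator column per subject (absorbing between-subject offsets).
#' The resulting residual variance feeds [bic()] and
#' [log_bayes_factor()] for measure comparison.
#'
#' @param measures A `measure_table` (or compatible data.frame).
#' @param method Which method's rows to use.
#' @return A `glm_fit` (k = 1 + number of subjects).
#' @export
condition_prediction_glm <- function(measures, method) {
  d <- measures[measures$method == method &
                  measures$condition != "CS+US", , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable rows for method ", method)
  subs <- unique(d$subject)
  if (length(subs) < 2L) stop("need at least 2 subjects")
  per_sub <- table(d$subject, d$condition)
  if (any(per_sub == 0))
    stop("every subject needs both CS- and CS+noUS trials")
  y <- ifelse(d$condition == "CS+noUS", 1, -1)
  S <- outer(d$subject, subs, "==") * 1
  X <- cbind(estimate = d$estimate, S)
  colnames(X) <- c("estimate", paste0("subject_", subs))
  fit_glm(y, X)
}

#' Within-subject CS main effect
#'
#' Paired contrast of per-subject CS+ and CS- summary means: `F = t^2` of
#' the paired t statistic with df (1, n_subjects - 1). With a
#' between-subject `group` factor (e.g. SOA groups) a mixed-design ANOVA
#' is used and the CS main effect extracted from the within-subject
#' stratum.
#'
#' @param cs_minus,cs_plus Per-subject mean responses (paired vectors).
#' @param group Optional between-subject factor.
#' @return List with `F`, `p`, `df`, and `degenerate` flag (TRUE when the
#'   contrast has zero within-subject variance, where F is unbounded).
#' @export
cs_main_effect <- function(cs_minus, cs_plus, group = NULL) {
  n <- length(cs_minus)
  stopifnot(length(cs_plus) == n)
  if (n < 2L) stop("need at least 2 subjects")
  diffs <- cs_plus - cs_minus
  if (is.null(group)) {
    sdd <- stats::sd(diffs)
    if (sdd == 0) {
      degen <- TRUE
      Fv <- if (mean(diffs) == 0) 0 else Inf
      p <- if (Fv == 0) 1 else 0
      return(list(F = Fv, p = p, df = c(1, n - 1), degenerate = degen))
    }
    tt <- mean(diffs) / (sdd / sqrt(n))
    Fv <- tt^2
    p <- stats::pf(Fv, 1, n - 1, lower.tail = FALSE)
    return(list(F = Fv, p = p, df = c(1, n - 1), degenerate = FALSE))
  }
  group <- factor(group)
  long <- data.frame(
    y = c(cs_minus, cs_plus),
    cs = factor(rep(c("CS-", "CS+"), each = n)),
    subject = factor(rep(seq_len(n), 2)),
    group = rep(group, 2))
  av <- stats::aov(y ~ cs * group + Error(subject / cs), data = long)
  tab <- summary(av)[["Error: subject:cs"]][[1]]
  row <- grep("^cs\\s*$", rownames(tab))
  list(F = tab[row, "F value"], p = tab[row, "Pr(>F)"],
       df = c(tab[row, "Df"], tab["Residuals", "Df"]), degenerate = FALSE)
}

#' One Rescorla-Wagner update
#'
#' `V <- V + alpha * (lambda - V)`.
#'
#' @param V_prev Associative strength before the trial.
#' @param alpha Learning rate in `[0, 1]`.
#' @param lam Reinforcement on this trial (0 or 1).
#' @return Updated associative strength.
#' @export
rw_update <- function(V_prev, alpha, lam) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  V_prev + alpha * (lam - V_prev)
}

#' Rescorla-Wagner associative-strength trace
#'
#' Returns the pre-update value on each trial (the expectation the subject
#' holds going into the trial), starting from `V0`; `V[t]` is computed
#' from the reinforcement sequence `lam[1..t-1]`.
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param lam 0/1 reinforcement sequence (one per trial of this CS).
#' @param V0 Initial associative strength (default 0.5).
#' @return Numeric vector, same length as `lam`.
#' @export
rw_trace <- function(alpha, lam, V0 = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  nt <- length(lam)
  if (nt == 0L) return(numeric())
  if (alpha == 0) return(rep(V0, nt))
  # V_post[t] = (1-alpha) V_post[t-1] + alpha lam[t]; pre-update trace is
  # V_post shifted one trial back
  post <- stats::filter(alpha * lam, 1 - alpha, method = "recursive",
                        init = V0)
  c(V0, as.numeric(post)[-nt])
}

#' Fit Rescorla-Wagner learning rates to trial-wise estimates
#'
#' Models the response estimates as `a + b * V`, where `V` is the
#' pre-update associative strength of the trial's CS under CS-specific
#' learning rates, and minimises the summed squared error jointly over
#' the learning rates and the shared linear map `(a, b)` (profiled out by
#' OLS at each candidate rate). A coarse grid over the rates seeds a
#' bounded quasi-Newton refinement.
#'
#' @param estimates Trial-wise response estimates, in trial order.
#' @param lam 0/1 reinforcement per trial (US delivered).
#' @param cs CS label per trial (`"CS-"` / `"CS+"`).
#' @param V0 Initial associative strength (default 0.5).
#' @param grid_n Grid resolution per learning rate (default 10).
#' @return List with `alpha` (named per CS), `a`, `b`, `r2`, `sse` and
#'   `identified` (FALSE when the estimates carry no variance, leaving
#'   the rates unconstrained).
#' @export
fit_rw <- function(estimates, lam, cs, V0 = 0.5, grid_n = 10) {
  n <- length(estimates)
  stopifnot(length(lam) == n, length(cs) == n)
  cs <- as.character(cs)
  levels_cs <- sort(unique(cs))
  if (any(table(cs) < 10))
    stop("need at least 10 trials per CS")
  if (stats::sd(estimates) == 0) {
    return(list(alpha = stats::setNames(rep(NA_real_, length(levels_cs)),
                                        levels_cs),
                a = mean(estimates), b = 0, r2 = 0, sse = 0,
                identified = FALSE))
  }
  V_of <- function(alphas) {
    # clamp: L-BFGS-B finite-difference steps can poke just past the box
    alphas <- pmin(pmax(alphas, 0), 1)
    V <- numeric(n)
    for (ci in seq_along(levels_cs)) {
      sel <- cs == levels_cs[ci]
      V[sel] <- rw_trace(alphas[ci], lam[sel], V0)
    }
    V
  }
  sse_of <- function(alphas) {
    V <- V_of(alphas)
    f <- stats::lm.fit(cbind(1, V), estimates)
    sum(f$residuals^2)
  }
  gr <- seq(0.05, 0.95, length.out = grid_n)
  combos <- as.matrix(expand.grid(rep(list(gr), length(levels_cs))))
  sses <- apply(combos, 1, sse_of)
  best0 <- combos[which.min(sses), ]
  opt <- stats::optim(best0, sse_of, method = "L-BFGS-B",
                      lower = rep(0, length(levels_cs)),
                      upper = rep(1, length(levels_cs)),
                      control = list(maxit = 200))
  alphas <- opt$par
  V <- V_of(alphas)
  f <- stats::lm.fit(cbind(1, V), estimates)
  sst <- sum((estimates - mean(estimates))^2)
  list(alpha = stats::setNames(alphas, levels_cs),
       a = unname(f$coefficients[1]), b = unname(f$coefficients[2]),
       r2 = 1 - sum(f$residuals^2) / sst, sse = sum(f$residuals^2),
       identified = TRUE)
}

#' Pairwise model comparison across response measures
#'
#' Fits the condition-prediction GLM for each method in the table and
#' reports per-method BIC plus the pairwise log-Bayes-factor matrix
#' (`logBF[i, j] = BIC_i - BIC_j`; positive favours method j).
#'
#' @param measures A `measure_table` with two or more methods.
#' @return Object of class `model_comparison`: list with `bic` (named
#'   vector), `log_bf` (matrix) and `fits`.
#' @export
compare_measures <- function(measures) {
  methods <- unique(measures$method)
  if (length(methods) < 2L) stop("need at least two methods to compare")
  fits <- lapply(methods, function(m) condition_prediction_glm(measures, m))
  names(fits) <- methods
  bics <- vapply(fits, bic, numeric(1))
  lbf <- outer(bics, bics, "-")
  dimnames(lbf) <- list(methods, methods)
  structure(list(bic = bics, log_bf = lbf, fits = fits),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model_comparison (condition-prediction GLMs)\n")
  cat("BIC by method:\n")
  print(round(x$bic, 4))
  cat("log Bayes factors (row vs column; positive favours column):\n")
  print(round(x$log_bf, 2))
  invisible(x)
}
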