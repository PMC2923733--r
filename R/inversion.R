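# Model inversion: estimate the most likely sudomotor inputs given an
# observed trace, the two response functions and design-derived
# constraints.
#
# Scheme: maximum a posteriori under Gaussian priors and hard bounds.
# The model trace is linear in every amplitude once bump timings are
# fixed, so the inversion alternates (i) a global penalised least-squares
# solve over all amplitudes (anticipatory, evoked, SF candidates, SCL
# drifts) with an active-set treatment of the bound constraints, and
# (ii) local quasi-Newton refinement of each anticipatory bump's
# (amplitude, timing, dispersion) on a window around its trial, with
# multi-start over timing on the first pass. The residual variance is
# re-estimated between iterations. Spontaneous fluctuations live on a
# fixed candidate grid (spacing >= 2 s, the 0.5 responses/s cap) whose
# amplitudes are shrunk towards zero by a zero-mean prior. The MAP
# solution is summarised by a Laplace/BIC-style approximate log-evidence
# used downstream for model comparison.

#' Inversion configuration
#'
#' @param n_ascr Anticipatory bumps per trial (1 or 2; with 2, the
#'   anticipation window is split in half and one bump estimated per half).
#' @param estimate_sf,estimate_scl Include SF / SCL drift inputs.
#' @param sf_spacing Spacing of the SF candidate grid in seconds (>= 2,
#'   enforcing the 0.5 responses/s cap).
#' @param escr_latency Fixed event-to-response delay of evoked bursts in
#'   seconds (typically the latency fitted by [fit_rf()]; default 1.9).
#' @param escr_dispersion,sf_dispersion,scl_dispersion Fixed bump SDs (s).
#' @param outer_iters Alternations of global amplitude solve and local
#'   timing refinement (default 8).
#' @param restarts Extra timing initialisations per bump on the first
#'   iteration (default 2).
#' @param maxit L-BFGS-B iteration cap per local refinement.
#' @param obj_tail Seconds of post-window signal entering each local
#'   objective (captures the decaying response; default 15).
#' @param amp_mean,amp_sd Anticipatory amplitude prior (units).
#' @param escr_amp_mean,escr_amp_sd Evoked amplitude prior (units).
#' @param sf_amp_sd,scl_amp_sd Zero-mean shrinkage SDs for SF/SCL.
#' @param amp_threshold Reporting threshold for SF/SCL event counts.
#' @return An object of class `invert_config`.
#' @export
invert_config <- function(n_ascr = 1L, estimate_sf = TRUE,
                          estimate_scl = TRUE, sf_spacing = 2,
                          escr_latency = 1.9, escr_dispersion = 0.3,
                          sf_dispersion = 0.3, scl_dispersion = 1,
                          outer_iters = 8L, restarts = 2L, maxit = 100L,
                          obj_tail = 15, amp_mean = 0.3, amp_sd = 1,
                          escr_amp_mean = 1.9, escr_amp_sd = 2,
                          sf_amp_sd = 0.3, scl_amp_sd = 0.2,
                          amp_threshold = 0.1) {
  if (!n_ascr %in% 1:2) stop("n_ascr must be 1 or 2")
  if (sf_spacing < 2)
    stop("sf_spacing must be >= 2 s (0.5 responses/s cap)")
  structure(as.list(environment()), class = "invert_config")
}

#' Build design-derived priors
#'
#' Places the anticipatory bump(s) inside each trial's anticipation
#' window (timing prior centred mid-window), fixes the evoked-response
#' delay, and lays SF/SCL candidate grids over the inter-trial intervals.
#'
#' @param design A `trial_design`.
#' @param cfg An `invert_config`.
#' @param rate Sampling rate the priors will be used at (Hz).
#' @return An object of class `prior_set` with per-parameter Gaussian
#'   priors (mean, sd) and hard bounds.
#' @export
build_priors <- function(design, cfg = invert_config(), rate = 10) {
  stopifnot(inherits(design, "trial_design"), inherits(cfg, "invert_config"))
  n <- nrow(design)
  if (any(design$soa * rate < 2))
    stop("anticipation window shorter than 2 samples")
  asc <- do.call(rbind, lapply(seq_len(n), function(i) {
    cs <- design$cs_onset[i]; us <- design$us_onset[i]
    soa <- design$soa[i]
    sub <- seq(cs, us, length.out = cfg$n_ascr + 1L)
    data.frame(trial = i, bump = seq_len(cfg$n_ascr),
               amp_mean = cfg$amp_mean, amp_sd = cfg$amp_sd,
               amp_lo = 0, amp_hi = 10,
               c_mean = (sub[-1] + sub[-length(sub)]) / 2,
               c_sd = (sub[2] - sub[1]) / 4,
               c_lo = sub[-length(sub)], c_hi = sub[-1],
               d_mean = min(1, soa / 4 / cfg$n_ascr),
               d_sd = 1, d_lo = 0.1, d_hi = soa / 2 / cfg$n_ascr)
  }))
  esc <- if (any(design$reinforced)) {
    i <- which(design$reinforced)
    data.frame(trial = i, center = design$us_onset[i] + cfg$escr_latency,
               dispersion = cfg$escr_dispersion,
               amp_mean = cfg$escr_amp_mean, amp_sd = cfg$escr_amp_sd,
               amp_lo = 0, amp_hi = 30)
  } else data.frame(trial = integer(), center = numeric(),
                    dispersion = numeric(), amp_mean = numeric(),
                    amp_sd = numeric(), amp_lo = numeric(),
                    amp_hi = numeric())
  itis <- iti_windows(design)
  sf <- scl <- NULL
  if (cfg$estimate_sf && nrow(itis) > 0) {
    sf <- do.call(rbind, lapply(seq_len(nrow(itis)), function(w) {
      cand <- seq(itis$start[w], itis$end[w] - 1e-9, by = cfg$sf_spacing)
      if (length(cand) == 0L) return(NULL)
      data.frame(after_trial = itis$after_trial[w], center = cand,
                 dispersion = cfg$sf_dispersion,
                 amp_mean = 0, amp_sd = cfg$sf_amp_sd,
                 amp_lo = 0, amp_hi = 5)
    }))
  }
  if (cfg$estimate_scl && nrow(itis) > 0) {
    scl <- do.call(rbind, lapply(seq_len(nrow(itis)), function(w) {
      data.frame(after_trial = itis$after_trial[w],
                 center = (itis$start[w] + itis$end[w]) / 2,
                 dispersion = cfg$scl_dispersion,
                 amp_mean = 0, amp_sd = cfg$scl_amp_sd,
                 amp_lo = -2, amp_hi = 2)
    }))
  }
  structure(list(ascr = asc, escr = esc,
                 sf = sf %||% data.frame(), scl = scl %||% data.frame(),
                 cfg = cfg),
            class = "prior_set")
}

# --- internal machinery -----------------------------------------------------

# Full-length unit response (amplitude 1) of one bump through its kernel.
# class_ "scr"/"sf": convolution; "scl": running integral (a step that
# persists to the end of the recording).
unit_response <- function(center, dispersion, class_, n, rate, t0,
                          k_scr, k_sf) {
  i0 <- max(1L, as.integer(floor((center - 5 * dispersion - t0) * rate)) + 1L)
  if (class_ == "scl") {
    i1u <- min(n, as.integer(ceiling((center + 5 * dispersion - t0) * rate)) + 1L)
    out <- numeric(n)
    if (i0 > n) return(out)
    tt <- t0 + (i0:i1u - 1) / rate
    u <- exp(-(tt - center)^2 / (2 * dispersion^2))
    seg <- cumsum(u) / rate
    out[i0:i1u] <- seg
    if (i1u < n) out[(i1u + 1L):n] <- seg[length(seg)]
    return(out)
  }
  k <- if (class_ == "sf") k_sf else k_scr
  i1u <- min(n, as.integer(ceiling((center + 5 * dispersion - t0) * rate)) +
               1L + length(k))
  out <- numeric(n)
  if (i0 > n) return(out)
  tt <- t0 + (i0:i1u - 1) / rate
  u <- exp(-(tt - center)^2 / (2 * dispersion^2))
  out[i0:i1u] <- conv_causal(u, k)
  out
}

# Penalised bounded least squares:
#   min ||y - D a||^2 / sigma2 + sum(((a - mu)/s)^2),  lo <= a <= hi
# solved by ridge normal equations with an active-set loop on the bounds.
solve_amplitudes <- function(D, y, mu, s, lo, hi, sigma2) {
  m <- ncol(D)
  DtD <- crossprod(D) / sigma2
  Dty <- drop(crossprod(D, y)) / sigma2
  P <- diag(1 / s^2, m)
  a <- pmin(pmax(mu, lo), hi)
  free <- rep(TRUE, m)
  for (pass in 1:25) {
    A <- DtD[free, free, drop = FALSE] + P[free, free, drop = FALSE]
    b <- Dty[free] + mu[free] / s[free]^2
    if (any(!free))
      b <- b - drop(DtD[free, !free, drop = FALSE] %*% a[!free])
    sol <- tryCatch(solve(A, b), error = function(e)
      drop(MASS_ginv_fallback(A) %*% b))
    a_new <- a
    a_new[free] <- sol
    viol <- free & (a_new < lo | a_new > hi)
    if (!any(viol)) {
      a <- a_new
      # KKT release check for clamped parameters
      if (any(!free)) {
        g <- drop(DtD %*% a) - Dty + (a - mu) / s^2
        rel <- (!free) & ((a <= lo & g < -1e-9) | (a >= hi & g > 1e-9))
        if (any(rel)) { free <- free | rel; next }
      }
      return(a)
    }
    a_new[viol] <- pmin(pmax(a_new[viol], lo[viol]), hi[viol])
    free[viol] <- FALSE
    a <- a_new
    if (!any(free)) return(a)
  }
  a
}

# minimal pseudo-inverse fallback for (numerically) singular systems
MASS_ginv_fallback <- function(A, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*%
    ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
}

#' Invert the forward model on an observed trace
#'
#' @param series An `sc_timeseries` (preprocessed or model-space).
#' @param design A `trial_design`.
#' @param rf_scr,rf_sf `response_function`s on the series rate.
#' @param priors A `prior_set` from [build_priors()]; built automatically
#'   from `cfg` when `NULL`.
#' @param cfg An `invert_config`; when `priors` is supplied its embedded
#'   config is used instead.
#' @param seed Integer seed controlling multi-start order.
#' @return An object of class `inversion_result`: per-trial anticipatory
#'   parameter estimates (`ascr`), evoked amplitudes (`escr`), SF/SCL
#'   events, residual variance `sigma_e2` (SSE/n), `n`, free-parameter
#'   count `k`, the fitted trace, `r2` and the approximate log-evidence
#'   (Gaussian log-likelihood at the MAP minus `k/2 log n`).
#' @export
invert <- function(series, design, rf_scr, rf_sf, priors = NULL,
                   cfg = invert_config(), seed = 1) {
  stopifnot(inherits(series, "sc_timeseries"), inherits(design, "trial_design"))
  if (is.null(priors)) priors <- build_priors(design, cfg, series$grid$rate)
  cfg <- priors$cfg
  grid <- series$grid
  if (abs(grid$rate - rf_scr$rate) > 1e-9 || abs(grid$rate - rf_sf$rate) > 1e-9)
    stop("response function rates must match the series rate")
  if (rf_scr$kind != "scr" || rf_sf$kind != "sf")
    stop("rf_scr must be of kind 'scr' and rf_sf of kind 'sf'")
  y <- series$values
  n <- grid$n; rate <- grid$rate; t0 <- grid$t0
  set.seed(seed)
  k_scr <- rf_scr$kernel; k_sf <- rf_sf$kernel

  pa <- priors$ascr; pe <- priors$escr; psf <- priors$sf; pscl <- priors$scl
  # one amplitude parameter per row of the stacked table
  tab <- rbind(
    data.frame(class = "ascr", trial = pa$trial, bump = pa$bump,
               center = pa$c_mean, dispersion = pa$d_mean,
               mu = pa$amp_mean, s = pa$amp_sd, lo = pa$amp_lo,
               hi = pa$amp_hi),
    if (nrow(pe)) data.frame(class = "escr", trial = pe$trial, bump = 1L,
                             center = pe$center, dispersion = pe$dispersion,
                             mu = pe$amp_mean, s = pe$amp_sd, lo = pe$amp_lo,
                             hi = pe$amp_hi),
    if (nrow(psf)) data.frame(class = "sf", trial = psf$after_trial,
                              bump = seq_len(nrow(psf)), center = psf$center,
                              dispersion = psf$dispersion, mu = psf$amp_mean,
                              s = psf$amp_sd, lo = psf$amp_lo,
                              hi = psf$amp_hi),
    if (nrow(pscl)) data.frame(class = "scl", trial = pscl$after_trial,
                               bump = seq_len(nrow(pscl)),
                               center = pscl$center,
                               dispersion = pscl$dispersion,
                               mu = pscl$amp_mean, s = pscl$amp_sd,
                               lo = pscl$amp_lo, hi = pscl$amp_hi))
  m <- nrow(tab)
  amp <- pmin(pmax(tab$mu, tab$lo), tab$hi)
  iasc <- which(tab$class == "ascr")

  D <- matrix(0, n, m)
  for (j in seq_len(m))
    D[, j] <- unit_response(tab$center[j], tab$dispersion[j], tab$class[j],
                            n, rate, t0, k_scr, k_sf)

  sigma2 <- max(1e-6, 0.05 * stats::var(y))
  plans <- new.env(parent = emptyenv())
  local_plan <- function(nloc) {
    key <- as.character(nloc)
    if (is.null(plans[[key]])) plans[[key]] <- make_conv_plan(nloc, k_scr)
    plans[[key]]
  }

  for (it in seq_len(cfg$outer_iters)) {
    amp <- solve_amplitudes(D, y, tab$mu, tab$s, tab$lo, tab$hi, sigma2)
    fit <- drop(D %*% amp)
    sigma2 <- max(1e-8, mean((y - fit)^2))
    # local refinement of anticipatory (amplitude, centre, dispersion)
    for (j in iasc) {
      row <- match(j, iasc)
      pr <- pa[row, ]
      i0 <- max(1L, grid_index(grid, pr$c_lo - 1))
      i1 <- min(n, grid_index(grid, pr$c_hi + cfg$obj_tail))
      nloc <- i1 - i0 + 1L
      plan <- local_plan(nloc)
      tt <- t0 + (i0:i1 - 1) / rate
      r <- (y - fit + amp[j] * D[, j])[i0:i1]
      negpost <- function(th) {
        u <- th[1] * exp(-(tt - th[2])^2 / (2 * th[3]^2))
        pred <- conv_plan_apply(plan, u)
        0.5 * sum((r - pred)^2) / sigma2 +
          0.5 * (((th[1] - pr$amp_mean) / pr$amp_sd)^2 +
                   ((th[2] - pr$c_mean) / pr$c_sd)^2 +
                   ((th[3] - pr$d_mean) / pr$d_sd)^2)
      }
      th_cur <- c(amp[j], tab$center[j], tab$dispersion[j])
      starts <- list(th_cur)
      if (it == 1L && cfg$restarts > 0) {
        fr <- utils::head(c(0.3, 0.7, stats::runif(5)), cfg$restarts)
        for (f in fr)
          starts[[length(starts) + 1L]] <-
            c(th_cur[1], pr$c_lo + f * (pr$c_hi - pr$c_lo), pr$d_mean)
      }
      best <- NULL
      for (th0 in starts) {
        opt <- try(stats::optim(th0, negpost, method = "L-BFGS-B",
                                lower = c(pr$amp_lo, pr$c_lo, pr$d_lo),
                                upper = c(pr$amp_hi, pr$c_hi, pr$d_hi),
                                control = list(maxit = cfg$maxit)),
                   silent = TRUE)
        if (inherits(opt, "try-error")) next
        if (is.null(best) || opt$value < best$value) best <- opt
      }
      if (is.null(best))
        stop("timing refinement failed for trial ", pr$trial)
      changed <- abs(best$par[2] - tab$center[j]) > 1e-9 ||
        abs(best$par[3] - tab$dispersion[j]) > 1e-9
      fit <- fit - amp[j] * D[, j]
      amp[j] <- best$par[1]
      tab$center[j] <- best$par[2]
      tab$dispersion[j] <- best$par[3]
      if (changed)
        D[, j] <- unit_response(tab$center[j], tab$dispersion[j], "scr",
                                n, rate, t0, k_scr, k_sf)
      fit <- fit + amp[j] * D[, j]
    }
    sigma2 <- max(1e-8, mean((y - fit)^2))
  }
  amp <- solve_amplitudes(D, y, tab$mu, tab$s, tab$lo, tab$hi, sigma2)
  fit <- drop(D %*% amp)
  sigma_e2 <- mean((y - fit)^2)

  sel <- tab$class == "ascr"
  ascr_out <- data.frame(trial = tab$trial[sel], bump = tab$bump[sel],
                         amplitude = amp[sel], center = tab$center[sel],
                         dispersion = tab$dispersion[sel])
  sel <- tab$class == "escr"
  escr_out <- if (any(sel))
    data.frame(trial = tab$trial[sel], amplitude = amp[sel],
               center = tab$center[sel])
  else data.frame()
  sel <- tab$class == "sf"
  sf_out <- if (any(sel))
    data.frame(after_trial = tab$trial[sel], center = tab$center[sel],
               amplitude = amp[sel])
  else data.frame()
  sel <- tab$class == "scl"
  scl_out <- if (any(sel))
    data.frame(after_trial = tab$trial[sel], center = tab$center[sel],
               amplitude = amp[sel])
  else data.frame()

  k <- m + 2L * length(iasc)  # each aSCR bump also has centre + dispersion
  loglik <- -n / 2 * (log(2 * pi * max(sigma_e2, 1e-12)) + 1)
  r2 <- 1 - sum((y - fit)^2) / max(sum((y - mean(y))^2), 1e-12)
  structure(list(ascr = ascr_out, escr = escr_out, sf = sf_out,
                 scl = scl_out, sigma_e2 = sigma_e2, n = n, k = k,
                 fitted = sc_timeseries(grid, fit, units = series$units),
                 r2 = r2,
                 logev = loglik - 0.5 * k * log(n),
                 amp_threshold = cfg$amp_threshold),
            class = "inversion_result")
}

# causal convolution with an FFT plan cached for a fixed local length
make_conv_plan <- function(nloc, kernel) {
  L <- stats::nextn(nloc + length(kernel) - 1L, 2)
  list(L = L, Kf = stats::fft(c(kernel, numeric(L - length(kernel)))),
       nloc = nloc)
}
conv_plan_apply <- function(plan, x) {
  xf <- stats::fft(c(x, numeric(plan$L - length(x))))
  Re(stats::fft(xf * plan$Kf, inverse = TRUE))[seq_len(plan$nloc)] / plan$L
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf(
    "inversion_result: %d trials, k = %d parameters, n = %d, sigma_e2 = %.4g, R2 = %.4f\n",
    length(unique(x$ascr$trial)), x$k, x$n, x$sigma_e2, x$r2))
  nsf <- if (nrow(x$sf)) sum(x$sf$amplitude > x$amp_threshold) else 0
  cat(sprintf("  SF events > %.2g units: %d; approx log-evidence %.1f\n",
              x$amp_threshold, nsf, x$logev))
  invisible(x)
}

#' Condition-wise summary of anticipatory amplitudes
#'
#' Averages the estimated per-trial anticipatory amplitude for CS- trials
#' and for CS+ trials not followed by a US; reinforced CS+ trials are
#' excluded so the evoked response cannot contaminate the conditioned
#' response summary.
#'
#' @param result An `inversion_result`, or a data.frame with `trial` and
#'   `amplitude` columns (one row per trial).
#' @param design The `trial_design`.
#' @return Named numeric: mean amplitude for `CS-` and `CS+noUS`.
#' @export
summarize_conditions <- function(result, design) {
  amp <- if (inherits(result, "inversion_result")) {
    trial_amplitudes(result)
  } else {
    stopifnot(is.data.frame(result))
    result$amplitude[order(result$trial)]
  }
  cond <- condition_labels(design)
  if (length(amp) != nrow(design))
    stop("one amplitude per trial required")
  out <- c(`CS-` = NA_real_, `CS+noUS` = NA_real_)
  for (cc in names(out)) {
    sel <- cond == cc
    if (!any(sel)) stop("no trials in condition ", cc)
    out[cc] <- mean(amp[sel])
  }
  out
}

#' Per-trial anticipatory amplitude vector
#'
#' With two bumps per window the larger amplitude is reported.
#'
#' @param result An `inversion_result`.
#' @return Numeric vector ordered by trial.
#' @export
trial_amplitudes <- function(result) {
  stopifnot(inherits(result, "inversion_result"))
  a <- result$ascr
  vapply(sort(unique(a$trial)),
         function(tr) max(a$amplitude[a$trial == tr]), numeric(1))
}
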