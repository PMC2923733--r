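# Conventional estimators used as benchmarks: baseline-corrected peak
# scoring within the anticipation window, and convolution GLMs (stick
# functions convolved with a canonical kernel, optionally with latency and
# dispersion derivative regressors and per-trial response reconstruction).

#' Peak scoring of an anticipatory response
#'
#' The maximum of the series over the scoring window minus the mean of a
#' 1 s pre-CS baseline. `EIR` (entire interval response) scores
#' `[CS onset, US onset)`, extended to `[CS onset, CS onset + 5 s)` when
#' the SOA is under 5 s to accommodate response latency. `FIR`/`SIR` score
#' the first/second half of the (unextended) anticipation window.
#'
#' @param series An `sc_timeseries`.
#' @param design A `trial_design`.
#' @param trial Trial number (row of `design`); vectorised if omitted.
#' @param mode `"EIR"`, `"FIR"` or `"SIR"`.
#' @param baseline Baseline duration before CS onset in seconds (default 1).
#' @return Amplitude(s): peak minus baseline mean, one per trial.
#' @export
peak_score <- function(series, design, trial = NULL,
                       mode = c("EIR", "FIR", "SIR"), baseline = 1) {
  stopifnot(inherits(series, "sc_timeseries"), inherits(design, "trial_design"))
  mode <- match.arg(mode)
  if (is.null(trial)) trial <- design$trial
  g <- series$grid
  vapply(trial, function(tr) {
    cs <- design$cs_onset[tr]; us <- design$us_onset[tr]
    soa <- design$soa[tr]
    win <- switch(mode,
                  EIR = if (soa < 5) c(cs, cs + 5) else c(cs, us),
                  FIR = c(cs, cs + soa / 2),
                  SIR = c(cs + soa / 2, us))
    b0 <- grid_index(g, cs - baseline); b1 <- grid_index(g, cs) - 1L
    if (b0 < 1L) stop("baseline window starts before the recording")
    i0 <- grid_index(g, win[1]); i1 <- min(g$n, grid_index(g, win[2]) - 1L)
    if (i0 > g$n) stop("scoring window outside the recording")
    max(series$values[i0:i1]) - mean(series$values[b0:b1])
  }, numeric(1))
}

# stick train on the grid: unit impulses at the given onsets
stick <- function(onsets, grid) {
  x <- numeric(grid$n)
  idx <- grid_index(grid, onsets)
  idx <- idx[idx >= 1L & idx <= grid$n]
  x[idx] <- x[idx] + 1
  x
}

# canonical kernel and its numerical partial derivatives w.r.t. a latency
# shift and the smoothing (dispersion) parameter, sampled on the grid rate
basis_kernels <- function(rf, basis, rel_step = 1e-3) {
  k0 <- rf$kernel
  if (basis == "canonical") return(list(canonical = k0))
  n <- length(k0); rate <- rf$rate
  p <- rf$shape
  kern_at <- function(lat, sg) {
    rf_fit_model(c(log(p[1]), log(p[2]), log(sg), lat, 1), n, rate) / rf$norm
  }
  h_lat <- max(rel_step, rel_step * 1)          # seconds
  h_sg <- rel_step * p[3]
  d_lat <- (kern_at(h_lat, p[3]) - kern_at(-h_lat, p[3])) / (2 * h_lat)
  d_sg <- (kern_at(0, p[3] + h_sg) - kern_at(0, p[3] - h_sg)) / (2 * h_sg)
  list(canonical = k0, d_latency = d_lat, d_dispersion = d_sg)
}

#' Build a convolution GLM design matrix
#'
#' Event onsets become stick functions convolved with the canonical
#' response function (and optionally its latency/dispersion partial
#' derivatives). In `"conditions"` mode events are grouped into the four
#' types CS-, CS+ not followed by US, CS+ followed by US, and US; in
#' `"trials"` mode each CS event and each US event gets its own column per
#' basis function.
#'
#' @param design A `trial_design`.
#' @param rf A `response_function` on the series grid.
#' @param grid The `time_grid` of the series to be fitted.
#' @param mode `"conditions"` or `"trials"`.
#' @param basis `"canonical"` or `"canonical+derivatives"`.
#' @return Object of class `glm_design`: list with `X` (n x k matrix),
#'   `labels` (data.frame with `event`, `trial`, `basis` per column),
#'   `kernels`, `mode`, `basis`.
#' @export
build_glm_design <- function(design, rf, grid,
                             mode = c("conditions", "trials"),
                             basis = c("canonical", "canonical+derivatives")) {
  stopifnot(inherits(design, "trial_design"),
            inherits(rf, "response_function"), inherits(grid, "time_grid"))
  mode <- match.arg(mode); basis <- match.arg(basis)
  if (abs(grid$rate - rf$rate) > 1e-9)
    stop("grid and response function rates differ")
  kerns <- basis_kernels(rf, basis)
  cond <- condition_labels(design)
  ev <- rbind(
    data.frame(onset = design$cs_onset, event = cond, trial = design$trial),
    if (any(design$reinforced))
      data.frame(onset = design$us_onset[design$reinforced], event = "US",
                 trial = design$trial[design$reinforced]))
  if (anyDuplicated(ev$onset))
    stop("two events share an onset; cannot build distinct regressors")
  groups <- if (mode == "conditions") {
    sp <- split(ev, ev$event)
    data.frame(label = names(sp), trial = NA_integer_,
               event = names(sp))[order(names(sp)), , drop = FALSE]
  } else {
    ev$label <- sprintf("%s_t%03d", ifelse(ev$event == "US", "US", "CS"),
                        ev$trial)
    unique(ev[order(ev$onset), c("label", "trial", "event")])
  }
  cols <- list(); labs <- list()
  for (gi in seq_len(nrow(groups))) {
    ons <- if (mode == "conditions") ev$onset[ev$event == groups$event[gi]]
           else ev$onset[ev$label == groups$label[gi]]
    s <- stick(ons, grid)
    for (bn in names(kerns)) {
      cols[[length(cols) + 1L]] <- conv_causal(s, kerns[[bn]])
      labs[[length(labs) + 1L]] <- data.frame(
        event = groups$event[gi], trial = groups$trial[gi],
        label = groups$label[gi], basis = bn, stringsAsFactors = FALSE)
    }
  }
  X <- do.call(cbind, cols)
  labels <- do.call(rbind, labs)
  if (any(colSums(abs(X)) == 0)) stop("design contains an all-zero column")
  if (ncol(X) >= grid$n) stop("more regressors than samples")
  colnames(X) <- paste(labels$label, labels$basis, sep = ".")
  structure(list(X = X, labels = labels, kernels = kerns,
                 mode = mode, basis = basis),
            class = "glm_design")
}

#' Ordinary least squares fit of a convolution GLM
#'
#' @param series An `sc_timeseries` (or numeric vector).
#' @param dm A `glm_design` (or plain design matrix).
#' @return Object of class `glm_fit`: `betas`, `sigma_e2` (SSE/n, the
#'   maximum-likelihood residual variance used by the BIC), `k` (number of
#'   regressors), `n`, `fitted`, plus the design labels.
#' @export
fit_glm <- function(series, dm) {
  y <- if (inherits(series, "sc_timeseries")) series$values else
    as.numeric(series)
  X <- if (inherits(dm, "glm_design")) dm$X else as.matrix(dm)
  n <- length(y); k <- ncol(X)
  if (k >= n) stop("need more samples than regressors")
  qr_x <- qr(X)
  if (qr_x$rank < k) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):k]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  sigma_e2 <- sum((y - fitted)^2) / n
  structure(list(betas = beta, sigma_e2 = sigma_e2, k = k, n = n,
                 fitted = fitted,
                 labels = if (inherits(dm, "glm_design")) dm$labels,
                 kernels = if (inherits(dm, "glm_design")) dm$kernels,
                 mode = if (inherits(dm, "glm_design")) dm$mode,
                 basis = if (inherits(dm, "glm_design")) dm$basis),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit: k = %d regressors, n = %d samples, sigma_e2 = %.4g\n",
              x$k, x$n, x$sigma_e2))
  invisible(x)
}

#' Reconstruct a trial's response peak from a derivative-basis fit
#'
#' With the informed basis (canonical kernel plus latency and dispersion
#' derivatives) the per-trial response is rebuilt as the beta-weighted sum
#' of the basis kernels; its maximum is an amplitude estimate free of the
#' latency-induced bias of the canonical-only beta.
#'
#' @param fit A `glm_fit` from a `"trials"`-mode,
#'   `"canonical+derivatives"`-basis design.
#' @param trial Trial number(s); default all CS trials.
#' @return Peak amplitude(s), one per trial.
#' @export
reconstruct_trial_peak <- function(fit, trial = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  if (is.null(fit$mode) || fit$mode != "trials" ||
      !identical(fit$basis, "canonical+derivatives"))
    stop("fit must come from a trials-mode design with derivative basis")
  lab <- fit$labels
  cs_rows <- lab[lab$event != "US", , drop = FALSE]
  if (is.null(trial)) trial <- sort(unique(cs_rows$trial))
  vapply(trial, function(tr) {
    sel <- which(lab$event != "US" & lab$trial == tr)
    if (length(sel) == 0L) stop("no columns for trial ", tr)
    resp <- numeric(length(fit$kernels[[1]]))
    for (i in sel)
      resp <- resp + fit$betas[i] * fit$kernels[[lab$basis[i]]]
    if (all(resp == 0)) 0 else max(resp)
  }, numeric(1))
}
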