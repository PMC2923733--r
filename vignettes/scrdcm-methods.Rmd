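---
title: "Model-based estimation of sudomotor activity from skin conductance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based estimation of sudomotor activity from skin conductance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrdcm)
```

## The generative model and its assumptions

Skin conductance is driven by sudomotor (sympathetic) nerve bursts whose
duration (well under 2 s) is short relative to the conductance responses
they evoke (tens of seconds). `scrdcm` models a conductance recording as
the output of a linear time-invariant system driven by parameterised
bursts:

* each burst is a Gaussian bump `a exp(-(t - mu)^2 / (2 sigma^2))`;
* anticipatory (aSCR) and evoked (eSCR) bursts share one response kernel
  and are summed **before** convolution; spontaneous fluctuations (SF)
  have their own, faster kernel; slow baseline (SCL) inputs are
  accumulated (integrated) rather than convolved;
* the four classes are constrained by the experimental design:
  anticipatory bursts live inside their trial's CS–US window, SF and SCL
  events in inter-trial intervals, with at most 0.5 SF per second;
* observation noise is iid Gaussian on the (filtered) trace — the
  simplest model consistent with the least-squares/Gaussian-evidence
  machinery of the statistics layer.

Assumptions worth keeping in mind: response kernels are constant within a
recording; a single (optionally double) Gaussian bump stands in for what
is physiologically probably a train of repeated bursts; and multi-channel
recordings, non-Gaussian burst shapes and biophysical sweat-gland
dynamics are out of scope.

### The kernel family and the sudomotor unit

No closed-form kernel is canonical in the electrodermal literature, so
the package uses a Gaussian-smoothed biexponential
`(exp(-t/tau1) - exp(-t/tau2)) ⊛ N(0, sigma_g^2)` for `t >= 0`: causal,
non-negative, skewed, with separate defaults for the SCR kernel
(`tau1 = 3.5`, `tau2 = 0.75`, `sigma_g = 0.5` s — slower recovery) and
the SF kernel (`2.0, 0.5, 0.3` s). Kernels are truncated at 30 s, where
they must have decayed below 1e-3 of their peak (enforced; the fitted
kernel's support is grown when a slow decay needs it).

Amplitudes are expressed in *sudomotor units*: kernels are rescaled so
that a reference bump of unit amplitude and 0.3 s dispersion produces a
peak deflection of exactly 1. Because the peak response grows with the
bump's dispersion, the unit must fix one reference dispersion; 0.3 s (the
evoked-burst default) is used.

## Preprocessing

`preprocess()` enforces the order band-pass → downsample → z-transform:
a bidirectional (forward–backward, hence zero-phase) first-order
Butterworth band-pass — cascaded one-pole high-pass at
`1/(2 pi * 10 s) = 0.0159 Hz` and low-pass at 5 Hz, each realised by
bilinear transform with reflect-padding of three time constants —
decimation to 10 Hz by sample picking, and a whole-series z-transform
(sample SD, `n - 1` denominator; the choice is conventional and
documented rather than consequential). The quoted cutoffs describe the
single pass; the bidirectional pass squares the magnitude response. The
z-transform uses the full filtered series; no edge trimming is applied.

## Estimating the response kernel and evoked latency

Evoked responses (to the US, and at US-omission times) are epoch-
extracted and summarised by the first principal component of the
column-centred epoch matrix; with amplitude as the main source of
between-trial variance, PC1 is proportional to the common response
shape. The kernel family plus a latency shift and free scale are then
least-squares fitted to PC1 (multi-start over log-spaced time
constants), and the fitted latency becomes the fixed evoked delay used
by the inversion.

Two numerical choices matter here:

* **Epoch window.** The default window is [0, 20) s, but `run_pipeline()`
  truncates it at the shortest US-to-next-CS gap: with short inter-trial
  intervals a long epoch contains the following trial's evoked response,
  whose presence/absence variance (reinforced vs unreinforced) dominates
  PC1 and destroys the fit.
* **Latency regularisation.** Latency and rise shape trade off almost
  freely in a 4-parameter kernel fit (a pure delay can be imitated by a
  slow rise or heavy smoothing). A mild ridge penalty pulls the log shape
  parameters towards the canonical kernel; it scales with the squared
  norm of the component, so the fit is invariant to the arbitrary scale
  of a principal component. Latency is bounded to [−2, 5] s. On synthetic
  cohorts generated with a 1.9 s latency the fitted latency averages
  ~1.85 s.

## Inversion

The inversion is maximum a posteriori under Gaussian priors with hard
bounds — a deliberately transparent stand-in for a full variational
treatment that preserves the Bayesian-deconvolution character and every
downstream statistic. Priors come from the design: anticipatory timing
is bounded by the anticipation window (prior centred mid-window, SD a
quarter of the window), dispersion bounded by [0.1 s, SOA/2], amplitude
prior 0.3 ± 1 units, evoked amplitude 1.9 ± 2 units, and SF/SCL
candidate amplitudes shrunk towards zero (SD 0.3 / 0.2). SF candidates
sit on a fixed ≥2 s grid per inter-trial interval, which converts a
variable-dimension burst-count problem into a fixed-dimension bounded
one while enforcing the 0.5/s cap literally.

Given bump timings the model trace is *linear in every amplitude*, so
the solver alternates:

1. a global penalised least-squares solve over all amplitudes (ridge
   normal equations with an active-set treatment of the bounds) — this
   resolves carry-over between neighbouring trials in closed form;
2. local L-BFGS-B refinement of each anticipatory bump's (amplitude,
   centre, dispersion) on a window extending ~15 s past its trial, with
   multi-start over timing on the first pass (seeded, deterministic);

with the residual variance re-estimated between iterations (8
alternations by default). This replaces a pure block-coordinate scheme,
which converged an order of magnitude more slowly on overlapping
designs. Model quality is summarised by the approximate log-evidence
`loglik(MAP) − (k/2) log n`, consistent with the BIC used for model
comparison; the residual variance convention is the maximum-likelihood
`SSE/n` throughout (consistency with the BIC formula matters more than
unbiasedness here).

Degenerate inputs behave sensibly: a flat trace shrinks all amplitudes
to (numerically) zero; unnecessary SF parameters never raise the
evidence beyond noise fluctuations.

## Benchmarks

Peak scoring subtracts a 1 s pre-CS baseline mean from the maximum over
the anticipation window ([CS, US), extended to CS + 5 s when the SOA is
under 5 s; EIR), or over its half-open halves split exactly at the
midpoint (FIR/SIR; the boundary ownership and the earliest-sample tie
rule are fixed conventions). The convolution GLM models each event onset
as a stick convolved with the canonical kernel — four condition
regressors or one regressor per event — optionally adding numerical
partial derivatives of the kernel with respect to latency and dispersion
(relative step 1e-3); the per-trial response is then reconstructed as the
beta-weighted basis sum and its peak read off, which suppresses the
latency-induced amplitude bias of the canonical-only beta.

## Statistics

`BIC = log(sigma_e^2) + (k/n) log(n)` (per-sample form; model-independent
constants dropped), and the log-Bayes factor between two response
measures is the difference of their condition-prediction-GLM BICs — with
equal complexity this is just the log variance ratio. The
condition-prediction GLM codes CS− as −1 and unreinforced CS+ as +1
(reinforced CS+ trials are excluded throughout so the evoked response
cannot leak into conditioned-response summaries), with per-subject
indicator columns absorbing between-subject offsets; the pooled-GLM
reading of the ambiguous per-participant wording is used and documented.
The CS main effect is the paired-contrast F (= t²) on per-subject
condition means, with an optional between-subject SOA factor via a
mixed-design ANOVA. Rescorla–Wagner fits profile the linear map (a, b)
out by OLS at each candidate learning rate (grid then bounded
refinement); V enters as the *pre-update* value — the expectation held
going into the trial — from V0 = 0.5. A Pearce–Hall variant is not
included: it would add an attention-weighted learning rate to the same
fitting harness without changing anything the validation suite measures.

## The synthetic world

`experiment_spec()` encodes two reference designs: 64 trials with SOA
4/10/16 s and ITIs 14/19/23 s ("exp1"), and 180 trials with SOA 3.5 s
and ITIs 7/9/11 s ("exp2"); 50% of CS+ trials are reinforced as an exact
count (permutation, not coin flips), never the CS−. Default response
parameters are the z-scale plausibility values: anticipatory amplitudes
1.02 (CS−) / 1.24 (CS+) ± 0.3 units, evoked amplitude 10.7 ± 1.5 units
(on the z scale the US response dwarfs conditioned responses), latency
1.9 s, SF rate 0.135 Hz at 0.29 units, ~0.14 signed SCL events per
trial at 0.18 units SD, observation noise 0.1. Anticipatory bump centres
sit at 60% of the window with mild jitter; dispersions at 1.1 ± 0.2 s.
The SF point process is Poisson thinned by a hard 2 s refractory
interval, with the proposal rate compensated (`lambda/(1 - 2 lambda)`)
so the realised long-run rate matches the requested one. In learning
mode, amplitudes are `a + b V` with CS-specific learning rates
(defaults α = 0.2, a = 0.3, b = 1.5, giving a late-session CS+/CS−
separation of roughly 0.7 units).

What a green test does and does not establish: the generator emulates
design geometry, component overlap, rate caps and learning dynamics, but
not electrode drift, movement artifacts, non-Gaussian noise, burst
trains, or kernel variability across trials — so recovery results bound
performance under the model's own assumptions, not under all real-world
violations of them.

## Scaling of the validation suite

The acceptance tests keep every stated threshold but scale simulation
*sizes* to desk scale: recovery sessions use 4–8 trials rather than 180,
and the 20-replicate cohort comparison uses 20 subjects × 20 trials with
a reduced-iteration inversion configuration (3 alternations, 1 restart).
The noise-recovery criterion itself runs the inversion at its default
settings, since it characterises the estimator rather than a speed
trade-off.

## Known limitations

* The MAP point estimate reports no posterior uncertainty; the evidence
  approximation is BIC-style, not a variational bound.
* Kernel and latency are only jointly identified; the reported split
  relies on the shape regularisation described above.
* The block-local timing refinement can in principle miss a global
  optimum on pathologically overlapping designs; the seeded multi-start
  mitigates but does not guarantee.
* Peak scoring inherits its known baseline sensitivity; it is included
  as a benchmark, not improved upon.
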