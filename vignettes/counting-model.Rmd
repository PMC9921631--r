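---
title: "Counting fluorophores from blinking time traces: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting fluorophores from blinking time traces: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorcount)
```

## The problem

In single-marker-switching nanoscopy (GSDIM, dSTORM and relatives), dye
molecules stochastically switch between fluorescent and dark states while a
camera records thousands of frames. The super-resolved image built from the
localizations has no absolute scale in fluorophore numbers: one molecule can
blink many times (overcounting) and molecules that never switch on are
missed (undercounting). `fluorcount` estimates the number `m` of
fluorophores inside a small evaluation region directly from the temporal
statistics of the region's background-corrected intensity trace, without
counting blinking events and without external calibration standards.

## The two-timescale model

Photophysical transitions span rates from `~1e12 s^-1` to less than
`min^-1`. The camera exposure (default 15 ms) splits them naturally:

* **Short timescale (sub-frame).** Everything faster than one frame —
  excitation/emission cycles and short-lived dark states — is summarized by
  the first two moments of the signal `Y` a single fluorophore emits in one
  frame *given it starts the frame bright*: the mean brightness `E(Y)` (in
  camera detector units) and the excess relative variance
  `sigma_e^2 = Var(Y)/E(Y)^2 - 1/E(Y)`, which is 0 for a purely Poissonian
  emitter and positive when a fast dark state intermittently gates the
  emission. The electron-multiplying camera register multiplies the
  shot-noise part of the variance by the excess noise factor `f^2` (2 for
  an EMCCD).

* **Long timescale (frame-to-frame).** A Markov chain over `r + 1` slow
  states: the bright state, `r - 1` reversible dark states and one
  absorbing bleached state, with per-frame transition matrix `T`
  ([`ltm_chain()`]). For Alexa 647 in a thiol buffer the chain has two
  reversible dark states (triplet-like DL1 and a long-lived thiol-adduct
  DL2), giving the 4-state [`alexa647_chain()`].

With `m` independent fluorophores, a fraction `nu` of them bright at frame
1 (the recording protocol drives `nu = 1` by UV pre-activation), the trace
moments are

* mean: `E(Y_t) = m E(Y) p_t` with `p_t` the bright occupancy,
  `p_t = sum_k (nu a0_k + (1-nu) a1_k) lambda_k^(t-1)` over the `r`
  transient eigenvalues `lambda_k` of `T`;
* variance: `Var(Y_t) = ((sigma_e^2 + 1) E(Y) + f^2 - E(Y_t)/m) E(Y_t)`;
* temporal covariance (`t < t'`):
  `Cov = m E(Y)^2 (g_tt' - p_t p_t')` with
  `g_tt' = p_t (T^(t'-t))[bright, bright]`.

The covariance construction treats per-frame emissions as conditionally
independent given the slow state path — the standard hidden-Markov
second-moment identity. It reproduces the variance formula on the diagonal
up to the within-frame emission terms, which only appear at `t = t'`.

At `nu = 1` the first frame gives the key identity `E(Y_1) = m E(Y)`: the
whole ensemble announces itself before switching begins. All counting in
this package descends from it.

## Estimators

**Gaussian pseudo log-likelihood** ([`fit_htmm()`]). The exact likelihood
of a trace under the model is a sum over all slow-state paths and is
intractable; the package maximizes instead the Gaussian surrogate
`l(gamma) = -1/2 [ (y - mu)' Sigma^-1 (y - mu) + log det Sigma ]` built
from the model's mean vector and covariance matrix on a subsampled frame
schedule. The free parameters are `m`, `E(Y)`, `sigma_e^2` and the chain's
transition probabilities (bright-row exits plus dark-state returns;
`DL1 <-> DL2` fixed to 0); `nu` and `f^2` are protocol constants. The
fitted chain's spectral form returns the amplitudes
`alpha_k = m E(Y) a0_k`, and `m = sum_k alpha_k / E(Y)` reproduces the
fitted count exactly because `sum_k a0_k = 1`.

**Simplified first-frame estimator** ([`simplified_estimate()`]).
`m ~ Y_1 / Ybar_blink`, where `Ybar_blink` is the mean of late
(`t > 2000`), isolated blink frames above `mu + 3 s`, with the first frame
of every blinking event discarded (a molecule switching on mid-frame is
not bright for the whole frame). It needs no optimization and is the
natural cross-check of the likelihood fit.

## Frame schedule

Estimation does not use all `N` recorded frames. The schedule keeps frames
1–20 densely (they carry the `m E(Y)` information) and thins later frames
on the power-law grid `t_j = round(19 + (j - 19)^beta)`,
`beta = log(N - 19)/log(n - 19)`, so the last index is exactly `N`
([`build_subsample_schedule()`]). Non-integer values are rounded to the
nearest frame and duplicates merged, so the schedule can be slightly
shorter than `n`. The protocol default is `N = 14060`, `n = 4000`; the
package's verification studies use `N = 2000`, `n = 400` (below).

## Numerical choices in the likelihood

* **Residual background noise.** A corrected trace still fluctuates around
  zero in dark frames with the spread `s` measured during region
  calibration. `Sigma` therefore receives a fixed `s^2` on its diagonal
  (`noise_sd` argument). This term is also what keeps the Gaussian
  surrogate well-posed: without it, synthetic traces whose dark frames are
  exactly zero let the likelihood diverge by shrinking dark-frame variance
  to zero.
* **Stabilizing jitter.** Before factorization, `1e-8 * mean(diag(Sigma))`
  is added to the diagonal, escalated tenfold up to `1e-4` before the
  evaluation fails; long schedules with eigenvalues near 1 make `Sigma`
  near-singular.
* **Degenerate ridge and the brightness band.** The surrogate has an
  unphysical ridge `E(Y) -> 0`, `m -> Inf`, `sigma_e^2 -> Inf` along which
  the model collapses to independent per-frame noise with a free variance
  profile — the mean and the variance profile stay perfect while the count
  loses all meaning, and on short schedules this ridge can out-score the
  truth. The fit therefore constrains `E(Y)` to within a factor 1.35 of a
  direct measurement of the single-fluorophore brightness — the density
  mode of the latest detected blink frames, the same physical information
  the simplified estimator uses — and caps `sigma_e^2` at 2, more than an
  order of magnitude above the ~0.1 measured for switching dyes. When a
  trace has no usable blink anchor the band widens to a factor 10.
* **Optimization.** Parameters are transformed to unconstrained scales
  (log for `m`, `E(Y)`, `sigma_e^2`; multinomial-logit for the bright-row
  exits; logit for the dark returns) and maximized with box-constrained
  L-BFGS-B: five starts (data-derived initialization plus jittered copies,
  the chain start taken from the canonical Alexa-647 timescale magnitudes
  `lambda = (0.9, 0.999, 0.99999)`), a short exploratory run from each,
  and a full polish of the best. Gradients are forward differences with a
  memoized base point. Fits are deterministic given the option seed.
* **Spectral decomposition.** Chains with complex or defective
  eigenstructure are rejected with a diagnostic naming the eigenvalues
  rather than silently using complex arithmetic; everything else works in
  matrix form, so such chains remain usable for simulation and fitting.
* **`nu < 1`.** The protocol keeps `nu = 1`; when a user sets `nu < 1`
  the non-bright initial mass is placed in the long-lived dark state by
  default (`dark_start_state`), a convention that is configurable.

## The synthetic-data generator

[`simulate_traces()`] and [`simulate_movie()`] emulate the measurement:

* slow-state paths per fluorophore from the chain, all bright at frame 1;
* a fluorophore contributes photons in a frame iff it *starts* the frame
  bright — matching the definition of `E(Y)`;
* per-bright-frame photon counts are Poisson with a gamma-distributed rate
  (shape `1/sigma_e^2`, scale `sigma_e^2 E(Y)`), which realizes
  `Var = sigma_e^2 E(Y)^2 + E(Y)` exactly and degenerates to Poisson at
  `sigma_e^2 = 0`;
* the EM register draws, for `n` photoelectrons, a gamma variable with
  shape `n` and scale `em_gain`, normalized back by the gain — the
  standard high-gain EM model, which doubles the Poisson variance
  (`f^2 = 2`); `f^2 = 1` skips the register (other values are refused);
* movie mode adds a planted third-degree polynomial background field, spots
  rendered as normalized 2-D Gaussians, optional background shot noise and
  Gaussian read noise, with all ground truth retained.

The generator reproduces the model's mean, variance and lag covariance —
the test suite verifies this against 4 Monte-Carlo standard errors — so
passing recovery tests demonstrates correctness of the estimation
machinery *on model-true data*. Real recordings additionally contain
out-of-focus emitters, drift, flat-field structure and dye-to-dye
brightness heterogeneity, none of which the generator emulates; recovery
results here do not bound those effects.

The default study conditions are `E(Y) = 1000` detector units,
`sigma_e^2 = 0.097`, `f^2 = 2`, and the [`alexa647_chain()`] defaults with
transient eigenvalues near `(0.9, 0.9992, 0.99999)` and a bleaching
probability of ~5% per switching cycle — a photostability consistent with
the order-of-a-hundred switching cycles this dye sustains in reducing
buffers, and necessary for the `t > 2000` single-molecule blink analyses
to have events to work with. Residual corrected-trace noise is 30 detector
units per single-molecule trace (`30 sqrt(m)` for `m` added traces).

## Background correction

The time-dependent background is fit per frame as a third-degree
polynomial `P_t(x, y)` over the 10-term basis
`{x^2, y^2, xy, x, y, 1, x^3, y^3, x^2 y, y^2 x}`, using only pixels not
flagged as signal. Signal pixels are found in the first
excitation-illuminated frame by a robust rule — median plus 5 MAD-sigmas,
dilated by 2 pixels to swallow PSF tails — plus all designated evaluation
regions. Cubic terms in raw 512-pixel coordinates are numerically
ill-conditioned, so the fit runs on coordinates rescaled to `[-1, 1]` and
converts the coefficients back to the raw pixel basis exactly. Each
region's trace is then corrected as
`Y_t = Y_t,measured - sum_(region pixels) P_t - mu`, where the
region-specific offset `mu` (and spread `s`) come from a Gaussian fit to
the Freedman–Diaconis histogram of the polynomial-subtracted trace with
iterative 3-s trimming to exclude blink frames. When traces are summed, a
second offset is estimated on the accumulated trace the same way.

## Characterization tools

* **Excess relative variance** ([`estimate_excess_variance()`]): per-trace
  `sigma_e^2` from retained blink frames, histogrammed, Gaussian-fit
  center reported. Additive read noise of spread `s` biases the estimate
  upward by about `s^2/E(Y)^2` — negligible for bright dyes.
* **Dwell-time analysis** ([`dwell_time_analysis()`]): times between
  consecutive blinking events, pooled over traces, fit with mixtures of
  1..K *geometric* components by EM — dwell times live on the frame grid,
  and a continuous exponential is rejected on large samples purely for its
  discretization mismatch. The smallest K not rejected by a Pearson
  chi-squared test at the 1% level is reported (BIC breaks ties when all
  are rejected). Event segmentation here uses a 5-sigma threshold rather
  than the 3-sigma blink rule: Gaussian background crosses 3 sigma at
  `1.35e-3` per frame, which would plant a spurious slow component at the
  inter-false-event timescale (~700 frames) into the histogram. Intervals
  truncated by the end of the recording never form (two events are
  required), which biases against very slow dark states.
* **Weighted multi-exponential fit** ([`fit_multiexponential()`]):
  Levenberg–Marquardt least squares of `sum_k alpha_k lambda_k^(t-1)`
  weighted by inverse per-frame standard deviations, default 3-component
  start `alpha = (20000, 100, 10)`, `lambda = (0.9, 0.999, 0.99999)`. If
  the fit is singular at the canonical start, the amplitudes are rescaled
  to the data once before failing. Note a trace must be several times
  longer than `1/(1 - lambda_k)` to resolve component `k`.
* **Labeling yield** ([`fit_conditional_binomial()`]): detected structures
  carry at least one dye, so per-structure counts follow
  `B(k | p, n)` conditioned on `k > 0`; `p` is estimated by maximum
  likelihood on the count histogram (equivalent to the least-squares fit
  on model-true histograms, and the defensible default otherwise), with a
  standard error from the observed Fisher information.

## Verification studies and problem sizes

The package ships its own verification harness ([`recovery_study()`]) and
an acceptance script (`scripts/acceptance.R`). The recovery studies run 45
ensembles at `m = 6` and 100 at `m = 50` with recordings of `N = 2000`
frames on an `n = 400` schedule — the added-trace experiments at desk
scale. At these sizes the pseudo-likelihood estimate of a single ensemble
has a standard deviation of roughly 30% of `m` (the information left after
subsampling), while the ensemble means recover the truth within a small
fraction of it. Moment checks use 20000 simulated single-fluorophore
traces; dwell studies use 60–80 traces of 4000–8000 frames; yield fits use
the published study sizes (380 structures at `n = 4`, 297 at `n = 6`).

## Known limitations

* The dense-Cholesky likelihood costs `O(n^3)` per evaluation in the
  schedule length; `n = 4000` fits are possible but slow. A structured
  (semiseparable) factorization would reduce this and is not implemented.
* The count is estimated per region independently; no information is
  shared across regions except through the labeling-yield fit.
* `sigma_e^2` and `E(Y)` are weakly separable on short schedules; the
  brightness band is what keeps the fit identified, and it requires the
  trace to contain late single-molecule blinks (true under the recording
  protocol, not necessarily for dyes that bleach within a few cycles).
* Camera artifacts (clock-induced charge, pixel non-uniformity), drift and
  out-of-focus light are outside the model and the generator.
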