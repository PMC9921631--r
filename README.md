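# fluorcount

Absolute fluorophore counting from blinking time traces in
single-marker-switching nanoscopy (GSDIM/dSTORM).

## The problem

Super-resolved images localize single molecules but carry no absolute
scale in fluorophore numbers: one dye blinks many times (overcounting)
and dyes that never switch on are missed (undercounting). `fluorcount`
estimates the number *m* of fluorophores in a small evaluation region
directly from the temporal statistics of the region's background-corrected
intensity trace — no blinking-event bookkeeping, no calibration standards,
no prior knowledge of photokinetic rates. It is aimed at quantitative
nanoscopy users who record intensity traces over regions of interest
(e.g. DNA-origami standards or labeled protein complexes).

## The model

A hidden two-timescale Markov model separates photophysics at the camera's
frame grid. Sub-frame dynamics are summarized by the per-bright-frame
signal moments — mean brightness E(Y) and excess relative variance
σ<sub>e</sub>² = Var(Y)/E(Y)² − 1/E(Y) — plus the EMCCD excess noise
factor f² ≈ 2. Frame-to-frame dynamics follow a Markov chain over a bright
state, reversible dark states and an absorbing bleached state (for Alexa
647: bright, DL1, DL2, bleached). With all m fluorophores bright at frame
1 (UV pre-activation, ν = 1):

- E(Y<sub>t</sub>) = m·E(Y)·Σ<sub>k</sub> α<sub>0,k</sub> λ<sub>k</sub><sup>t−1</sup>, with Σ<sub>k</sub> α<sub>0,k</sub> = 1
- Var(Y<sub>t</sub>) = ((σ<sub>e</sub>² + 1)E(Y) + f² − E(Y<sub>t</sub>)/m)·E(Y<sub>t</sub>)
- Cov(Y<sub>t</sub>, Y<sub>t′</sub>) = m·E(Y)²·(g<sub>tt′</sub> − p<sub>t</sub>p<sub>t′</sub>)

Two estimators of m are provided:

- **Pseudo log-likelihood** (`fit_htmm()`): maximize
  −½[(y−μ)ᵀΣ⁻¹(y−μ) + log det Σ] over (m, E(Y), σ<sub>e</sub>², chain
  probabilities) on a power-law frame schedule; m also follows from the
  fitted exponential amplitudes as m = Σ<sub>k</sub> α<sub>k</sub>/E(Y).
- **Simplified first-frame estimator** (`simplified_estimate()`):
  m ≈ Y₁ / Ȳ<sub>blink</sub>, the first-frame signal over the mean
  brightness of late isolated blink frames.

The package also contains the supporting instrumentation: a synthetic-data
generator with realistic photon statistics and EMCCD amplification,
time-dependent polynomial background correction with per-region offset
calibration, and characterization tools (excess-variance estimation,
dwell-time dark-state counting, weighted multi-exponential decay fits,
conditional-binomial labeling-yield fits). See the methods vignette
(`vignettes/counting-model.Rmd`) for the full model account.

## Worked example

Simulate one region containing 6 Alexa-647-like fluorophores
(E(Y) = 1000 detector units, σ<sub>e</sub>² = 0.097, f² = 2, residual
background noise 73 du), then count them both ways:

```r
library(fluorcount)

pars <- htmm_params(m = 6, chain = alexa647_chain(),
                    emission = emission_model(1000, 0.097, 2))
trace <- simulate_traces(pars, n_frames = 2000, n_traces = 1,
                         read_noise_sd = 73, seed = 7, format = "matrix")[1, ]

schedule <- build_subsample_schedule(N = 2000, n = 400)
fit <- fit_htmm(trace, schedule, noise_sd = 73)
fit
#> <htmm_fit> m_hat = 5.953  (integer 6 ) pseudo-logLik = -2368.6394
#>   E(Y) = 985.03  sigma_e^2 = 0.0267

glance(fit)
#> # A tibble: 1 × 6
#>   m_hat m_int m_from_amplitudes logLik convergence n_frames_used
#>   <dbl> <int>             <dbl>  <dbl>       <int>         <int>
#> 1  5.95     6              5.95 -2369.           0           400

simplified_estimate(trace, list(mu = 0, s = 73), min_frame = 700)
#> <simplified_estimate> m_hat = 5.729  (Y1 = 5893.399 , Ybar_blink = 1028.7 )
```

The fit recovers the planted count (m̂ = 5.95 → 6 of 6) and brightness
(985 vs 1000 du); `m_from_amplitudes` is the count re-derived from the
fitted exponential amplitudes and agrees with the directly fitted m. The
simplified estimator lands at 5.7 from one division. `tidy(fit)` exposes
the fitted transition probabilities, and `autoplot(fit)` overlays the
fitted mean decay on the schedule-frame data.

For camera movies, the same analysis starts from
`identify_signal_pixels()` → `fit_background_stack()` →
`extract_region_trace()` → `estimate_region_offset()` →
`correct_trace()`; `run_pipeline()` sequences everything, and
`inst/cli/fluorcount.R` exposes the pipeline as a shell command
(`simulate`, `correct`, `count`, `characterize`, `run`).

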