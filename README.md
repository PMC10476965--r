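# srmdecode

Encoding and decoding analyses for dentate gyrus granule cells of different
maturational ages. Adult neurogenesis places young, biophysically distinct
granule cells next to mature ones; this package provides the full modeling
pipeline for asking what that heterogeneity does to stimulus coding:

- **Stimuli** — discretized Ornstein–Uhlenbeck currents
  (`η(t+Δt) = η(t)e^{−Δt/τ} + √(1−e^{−2Δt/τ}) N(0,1)`, τ = 3 ms),
  theta-modulated Gaussian stimuli sampled by Cholesky factorization of
  `ρ(u) = σ² cos(2πfu) e^{−u/τ}`, correlated stimulus pairs, scaling to pA,
  and variance-preserving noise corruption.
- **Spike-train metrics** — coincidence counts with an 8 ms rectangular
  window, coincidence ratio, trial-to-trial reliability, Md similarity,
  edge-corrected PSTH, stimulus–PSTH cross-correlation, spike-time shuffling
  controls, passive-property fits, and threshold spike detection.
- **Spike response model (SRM)** — subthreshold voltage
  `v(t) = v_b + ∫k(u) i(t−u)du + Σ h_v(t−t_s)`, conditional intensity
  `λ(t) = exp((v − v_th − Σ h_th(t−t_s))/Δv)`, Bernoulli spiking with
  `P = 1 − e^{−λΔt}`; filters on rectangular bases (44×8 ms, 17×25 ms,
  18×25 ms).
- **Two-stage fitting** — masked least squares (QR) for the subthreshold
  parameters; concave penalized maximum likelihood with Newton ascent for
  `(Δv, v_th, h_th)`, the smoothness penalty selected on validation trials;
  validation by RMSE, bits/spike versus a rate-matched Poisson reference,
  and Md between simulated and recorded trains.
- **Bayesian decoding** — MAP reconstruction of the stimulus under the
  tridiagonal AR(1) prior, banded-Cholesky Newton with Laplace uncertainty
  (Takahashi inverse diagonal), r², Gaussian mutual information in bits,
  spike-triggered uncertainty profiles, and trial-count equalization
  `round(n/(λT))`.
- **Populations and pattern separation** — greedy construction of
  decoding-optimized populations (with mature-only constrained and random
  baselines, selection census, bootstrap relative MSE), and a discrimination
  task that classifies which of two correlated stimuli (ρ up to 0.9997) was
  encoded by comparing reconstruction errors.
- **Synthetic cohorts** — an age-structured ground-truth generator (20
  four-week, 17 five-week, 18 mature cells by default) reproducing the
  maturation orderings of filter timescale, resistance, and post-spike
  amplitudes, with per-cell drive calibrated to a target rate, so every
  stage of the pipeline is testable end to end without raw recordings.

## Worked example

```r
library(srmdecode)

# 1. a synthetic mature-like granule cell with drive calibrated to ~2 Hz
pool <- sample_cohort(cohort_spec(n_cells = c(0, 0, 1), seed = 1))
cell <- pool$cells[[1]]

# 2. synthesize a training recording and refit the SRM from it
recs <- synthesize_recordings(pool, protocol_spec(train_duration_ms = 40000,
                                                  dt = 0.2), seed = 2)
fit <- fit_srm(recs[[1]]$train, cfg = fit_config(alpha_grid = 0))
fs <- filter_summary(fit$params$k_coefs, fit$params$bases$k)

# 3. decode a fresh 2 s stimulus from nine spike trains of the fitted cell
n <- 2000
eta <- sample_ou(ou_spec(tau = 3, dt = 1, duration = n, seed = 3))
current <- scale_stimulus(eta, cell$scaling)
trains <- lapply(1:9, function(i) simulate_srm(fit$params, current, seed = 3 + i)$spikes)
dec <- map_decode(encoder_bank(list(list(params = fit$params,
                                         scaling = cell$scaling,
                                         trains = trains))),
                  prior_spec(tau = 3, dt = 1, n = n), eta_true = eta$values)
```

This prints (via the `cat` calls in `analysis/`-style drivers):

```
cell mature_01: tau_k 23.0 ms, R 254 MOhm, rate 2.15 Hz
refit: tau_k 23.0 ms, R 255 MOhm, vth -49.8 mV, delta_v 0.90 mV
decode: r2 = 0.07, info = 47 bits, mean posterior sd = 0.94
```

The refit recovers the generative membrane filter essentially exactly from
40 s of data; a single 2 Hz cell explains only a few percent of the
stimulus variance on its own (`r2 = 0.07`), which is precisely why the
population analyses matter — reconstruction improves monotonically as
greedily selected cells (often immature ones, despite their individually
worse performance) are added.

## Analysis workflow

The `analysis/` scripts run the study's analyses at desk scale over the
package, writing tables under `results/`:

1. `01_simulate_cohort.R` — draw and calibrate the 55-cell pool.
2. `02_fit_srm.R` — synthesize recordings and refit the SRM per cell;
   recovery and validation table.
3. `03_decode_single.R` — single-cell decoding; r²/information versus rate
   and their residuals; spike-triggered uncertainty.
4. `04_population_greedy.R` — greedy, constrained, and random populations;
   selection census; bootstrap relative MSE.
5. `05_discrimination.R` — discrimination accuracy by separation level and
   noise corruption, mixed versus mature populations.

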