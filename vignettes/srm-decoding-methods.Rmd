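---
title: "Encoding and decoding with spike response models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding and decoding with spike response models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
stimulus model, the spike response model (SRM) and its two-stage estimator,
the Bayesian decoder, the population and pattern-separation analyses, and the
design choices made where the problem left the design open. The pipeline is
aimed at the dentate gyrus, where adult neurogenesis produces granule cells
(GCs) of different maturational ages side by side; the question throughout is
how that age heterogeneity shapes stimulus encoding and decoding.

## Stimuli

Cells are driven with frozen fluctuating currents built from a zero-mean,
unit-variance Ornstein--Uhlenbeck (OU) process with correlation time
$\tau = 3$ ms, discretized exactly as the AR(1) recursion
$$\eta(t+\Delta t) = \eta(t)\,e^{-\Delta t/\tau} +
\sqrt{1-e^{-2\Delta t/\tau}}\;\mathcal N(0,1), \qquad \eta(0)\sim\mathcal N(0,1),$$
so every sample is marginally standard normal (`sample_ou()`). Currents in pA
are affine transforms $i(t) = \sigma\eta(t) + \mu$ (`scale_stimulus()`); the
per-cell $(\mu, \sigma)$ mimic the experimental practice of adapting the
drive to each cell's input resistance to reach a working firing rate.

Theta-modulated stimuli with autocovariance
$\rho(u) = \sigma^2 \cos(2\pi f u)\, e^{-u/\tau}$ ($f = 8$ Hz,
$\tau = 100$ ms) are sampled exactly by Cholesky factorization of the dense
covariance matrix (`sample_theta()`); a guard caps the matrix size, and a
small diagonal jitter (starting at $10^{-10}\sigma^2$, recorded in the trace
metadata) is added only if the factorization fails numerically. The spectral
peak of such stimuli is broad (a Lorentzian pair of half-width
$1/2\pi\tau \approx 1.6$ Hz), so `spectral_peak()` refines the argmax of the
averaged periodogram by fitting a mirrored Lorentzian pair plus a flat floor;
the raw argmax jitters by several 0.1 Hz bins even after averaging one
hundred 10 s periodograms, while the model fit is stable to about 0.03 Hz.

Correlated stimulus pairs for the pattern-separation task follow the same
recursion with innovation covariance
$K = \begin{pmatrix}1&\rho\\ \rho&1\end{pmatrix}$, giving two marginally
standard OU processes with instantaneous correlation $\rho$
(`sample_pair()`). The named separation levels are low $\rho = 0.9997$,
medium $0.999$, high $0.99$.

**Noise corruption.** The discrimination analysis corrupts each cell's copy
of the stimulus, but the corruption model itself was an open choice. We use
the variance-preserving mixture
$\sqrt{1-\nu^2}\,\eta + \nu\,\xi$ with $\xi$ an independent OU draw of the
same $\tau$, because it keeps the corrupted stimulus inside the stationary
distribution the decoder's prior assumes; the correlation with the original
is exactly $\sqrt{1-\nu^2}$. The level $\nu$ is recorded in the trace
metadata.

## Spike-train statistics

Coincidences use the rectangular kernel of width $\Delta = 8$ ms (about one
action potential): spikes $t_a, t_b$ are coincident when
$|t_a - t_b| \le \Delta/2$, with the boundary counted (closed window; the
convention is tested). From the pairwise counts come the coincidence ratio
between two trial sets, the within-set reliability (diagonal excluded), and
the Md similarity, which renormalizes across-set coincidences by each set's
internal reliability. Reliability and Md live in $[0, 1+\epsilon]$: a spike
can have several partners inside one window, so values slightly above 1 are
possible and are left uncorrected. For independent Poisson trains of rate
$\lambda$ the expected reliability is the chance level $\lambda\Delta$,
which the spike-time shuffling control (`shuffle_times()`) reproduces.

The PSTH uses a rectangular sliding window (default 40 ms; the width is a
free parameter and is stored with the output) and an edge correction that
spreads each spike's mass over the bins whose window covers it, so the
integral of the rate times trial count equals the spike count exactly.
Stimulus--PSTH cross-correlations are Pearson correlations of mean-subtracted
overlapping segments, lags limited to $\pm 200$ ms, positive lag meaning the
response trails the stimulus.

## The spike response model

The SRM is a GLM-style point process. Subthreshold voltage:
$$v(t) = v_b + \int_0^t k(u)\, i(t-u)\, du + \sum_{t_s} h_v(t - t_s),$$
conditional intensity
$\lambda(t) = \exp\{(v(t) - v_{th} - \sum_{t_s} h_{th}(t-t_s))/\Delta v\}$,
and a spike in each bin with probability $1 - e^{-\lambda(t)\Delta t}$.
$\lambda$ is in 1/ms so $\lambda \Delta t$ is dimensionless; the exponent is
clipped at +20 in simulation (+30 in fitting/decoding) with clip events
counted. All three filters live on rectangular bases: $k$ on 44 bins of
8 ms, $h_v$ on 17 bins of 25 ms starting at 25 ms, $h_{th}$ on 18 bins of
25 ms from 0. `srm_params` store $k$ as a density (mV/pA/ms) so the model is
independent of the simulation grid.

Two conventions matter and are shared exactly between simulator and fitter:
the stimulus convolution is causal with $k(0)$ acting on the current bin,
and post-spike filters act from the bin *after* the spike (the formal sum
includes lag 0, but applying $h_{th}(0)$ at the spike's own bin would make
generation acausal). There is no voltage reset and no action-potential
waveform; the first 25 ms after each spike are simply outside the
subthreshold model.

## Two-stage estimation

Stage 1 minimizes the squared error of the linear-in-parameters subthreshold
prediction after masking 25 ms of voltage from each spike (mask rows are
flagged, not dropped, and sentinel tests confirm masked samples can never
influence the estimate). The solution uses QR factorization rather than the
normal equations, with which it agrees on well-conditioned problems.

Stage 2 fixes the stage-1 prediction and maximizes the point-process
log-likelihood
$\sum_{t_s}\log\lambda(t_s) - \int\lambda$ in the reparameterization
$\theta_{th} = \Delta v^{-1}(1, v_{th}, c_1 \ldots c_M)$, which makes the
problem concave; Newton ascent with step halving runs to a gradient norm
below $10^{-6}$ (default, configurable), initialized at
$\Delta v_0 = 1$ mV and a threshold two standard deviations above the mean
predicted voltage. A smoothness penalty $-\alpha\sum(c_{m+1}-c_m)^2$ is
applied to the threshold-filter components of $\theta_{th}$ (i.e., to
$c_m/\Delta v$) — penalizing the unscaled $c_m$ would destroy concavity —
and $\alpha$ is chosen from the grid $\{0, 0.1, 1, 10, 100, 1000\}$ by the
largest unpenalized log-likelihood on the validation trials.

One numerical property worth knowing: the likelihood is the standard
point-process (Poisson) form while generation is Bernoulli per bin, so the
threshold-stage estimates carry a discretization bias of order
$\lambda\Delta t$ at spike times. At the native 0.1 ms grid the bias is
within a few percent for $\Delta v$ and well under one percent for
$v_{th}$; at a 0.5 ms grid it reaches tens of percent for $\Delta v$. Fits
should therefore use the acquisition grid, as the recording protocol does.

Fit quality is reported as validation RMSE (same 25 ms mask), a normalized
log-likelihood in bits per spike relative to a rate-matched homogeneous
Poisson reference, and the Md similarity between nine simulated and nine
recorded validation trains.

## Bayesian decoding

Given spike trains from one or more cells with known SRM parameters, the
normalized stimulus is reconstructed as the MAP estimate under the exact
AR(1) prior of the generator, whose precision is tridiagonal with
$\beta = e^{-\Delta t/\tau}$. The log-posterior is concave; Newton ascent
uses banded Cholesky solves, since the likelihood Hessian's bandwidth equals
the membrane-filter support in bins. The banded factor also yields the
Laplace posterior's log-determinant and, via the Takahashi (selected
inverse) recurrence — exact on the band — the per-time posterior standard
deviation. Mutual information is the Gaussian prior entropy minus the
average Laplace conditional entropy,
$I = \tfrac12(\overline{\log\det C^{-1}} - \log\det\Sigma^{-1})/\log 2$
bits, which is exactly zero with no observations and non-negative always.
The printed entropy formula in the source material carries a typographical
square root; we use the standard $\tfrac12\log\{(2\pi e)^N|\Sigma|\}$.

The decoding grid is a parameter. The native choice is the simulation grid;
decoding-heavy analyses (populations, discrimination, the bundled drivers
and tests) generate and decode on a common 1 ms grid, which keeps the
Hessian bandwidth at ~345 and each decode in seconds. Stimulus, spikes and
likelihood always share one grid — no cross-grid resampling is performed —
and information values are only compared within a fixed grid, since Gaussian
entropies scale with the number of bins.

Rate disparities between cells are equalized by giving each cell
$\mathrm{round}(n/(\lambda T))$ trials (floored at 1) so each contributes
about $n$ spikes; the single-cell protocol targets 140 spikes, the
population protocol 1200.

## Populations and pattern separation

Greedy populations start from a given cell and repeatedly add the candidate
(chosen with replacement) whose addition maximizes mean reconstruction $r^2$
over freshly sampled stimuli. Within a step all candidates share the same
stimulus seeds and the current members' simulated trains (common random
numbers), so comparisons are paired; exact ties go to the lowest cell id
and are counted. A constrained variant restricts the first $k$ steps to
mature cells; the random baseline draws uniformly with replacement. Group
differences in reconstruction error are summarized as bootstrap ratios of
group-mean MSE per population size with symmetric 95% percentile intervals.

The discrimination task encodes one member of a correlated pair — each cell
receiving its own corrupted copy, the corruption unknown to the decoder —
and classifies by comparing reconstruction MSE against both members. Exact
MSE ties (possible on coarse grids, measure zero otherwise) are counted
incorrect, a conservative convention; the encoded member alternates
deterministically across pairs to cancel any asymmetry of the pair
construction.

## Synthetic cohorts

The generator stands in for the recorded cells. Cohort centers follow the
maturation trends of the recordings — immature cells have slower, larger
membrane filters (default $\tau_k \approx 55/40/25$ ms and
$R \approx 450/350/250$ M$\Omega$ for 4-week/5-week/mature), weaker
post-spike kicks ($h_{v,1} \approx -0.5/-1.5/-3$ mV) and weaker threshold
deflections ($h_{th,1} \approx 2/4/6$ mV) — with lognormal dispersion
(CV 0.12) for positive scale parameters and normal dispersion for voltages.
These centers are design choices that reproduce the orderings, not measured
values; the absolute parameters of real cells are out of scope. Each cell's
drive is calibrated by bisection on $\mu$ (with $\sigma = \mu/2$) to a
common target rate (default 2 Hz, tolerance 10%) under common random
numbers. The default protocol mirrors the experiment: one 99 s training
trial, nine 10 s validation trials sharing a single stimulus template scaled
per cell, at 10 kHz, with 0.3 mV Gaussian voltage observation noise.

What passing tests on these cohorts do show: the estimators recover the
generative model, the decoder matches dense-linear-algebra oracles, and the
qualitative age effects (reliability, decoding residuals, population
composition, discrimination) have the expected directions. What they cannot
show: agreement with real GC parameter values, robustness to action
potential waveforms, electrode artifacts, non-stationarity, or model
mismatch in real recordings — the SRM is the generator here, so model
mismatch is limited to discretization and noise.

## Problem sizes and numerics

The bundled analysis drivers and the test suite run scaled-down versions of
each analysis (40 s training at 0.2 ms for the fitting driver; 1.5–2 s
stimuli on the 1 ms decode grid; pools of 9–18 cells; 16–40 discrimination
pairs), chosen so each stage finishes in minutes on one core while leaving
every estimator identical to the full protocol. Newton iterations are
capped at 100 with step halving and fail loudly rather than return
unconverged results. Banded factorizations reject non-positive-definite
input; the theta covariance jitters before failing. Degenerate inputs
(empty trains where a statistic needs spikes, zero-variance stimuli,
rank-deficient designs, rates outside the calibratable range) raise errors
with diagnoses rather than propagate NaN.

## Known limitations

The decoder assumes the OU prior; theta-stimulus decoding under its exact
covariance is an extension point, not implemented. The real-data loader
reads a plain-text export layout and is exercised only on synthetic
round-trips in this repository. Conductance-based stimulation, recurrent
connectivity between cells, and the linear discriminant age classifier are
out of scope.
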