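#' Rectangular filter basis
#'
#' Contiguous equal-width rectangular basis functions \eqn{f_j(t)} with
#' support `[start + (j-1)*width, start + j*width)`.
#'
#' @param n_bins number of bins.
#' @param width bin width (ms).
#' @param start left edge of the first bin (ms).
#' @return A `basis_spec` list with `n_bins`, `width`, `start`, `support`
#'   (total support end, ms).
#' @export
basis_spec <- function(n_bins, width, start = 0) {
  stopifnot(n_bins >= 1, width > 0, start >= 0)
  structure(list(n_bins = as.integer(n_bins), width = width, start = start,
                 support = start + n_bins * width),
            class = "basis_spec")
}

#' Default filter bases of the granule-cell SRM
#'
#' Membrane filter k: 44 bins of 8 ms from 0 ms; post-spike voltage filter
#' h_v: 17 bins of 25 ms starting at 25 ms (the first 25 ms after a spike are
#' outside the subthreshold model); post-spike threshold filter h_th: 18 bins
#' of 25 ms from 0 ms.
#'
#' @return A named list of three [basis_spec()] objects: `k`, `hv`, `hth`.
#' @export
default_bases <- function() {
  list(k = basis_spec(44, 8, 0),
       hv = basis_spec(17, 25, 25),
       hth = basis_spec(18, 25, 0))
}

#' Index of the basis bin containing each time
#' @param basis a [basis_spec()].
#' @param t vector of times (ms).
#' @return Integer bin indices (NA outside the support).
#' @export
basis_bin <- function(basis, t) {
  j <- floor((t - basis$start) / basis$width) + 1
  j[t < basis$start | j > basis$n_bins] <- NA_integer_
  as.integer(j)
}

#' Evaluate a filter (basis expansion) at arbitrary times
#' @param coefs coefficient per basis bin.
#' @param basis a [basis_spec()].
#' @param t times (ms).
#' @return Filter values; 0 outside the support.
#' @export
eval_filter <- function(coefs, basis, t) {
  stopifnot(length(coefs) == basis$n_bins)
  j <- basis_bin(basis, t)
  out <- numeric(length(t))
  ok <- !is.na(j)
  out[ok] <- coefs[j[ok]]
  out
}

#' Spike response model parameters
#'
#' The full encoder of one cell. The membrane filter `k_coefs` is stored as a
#' density in mV/(pA ms): convolved with a current in pA on a grid of step
#' `dt`, each sample contributes `k_coefs[bin] * dt` mV, so the parameters are
#' independent of the simulation grid. The post-spike filters `hv_coefs`
#' (membrane kick) and `hth_coefs` (threshold deflection) are in mV.
#'
#' @param vb voltage bias (mV).
#' @param k_coefs membrane filter density per k-basis bin (mV/pA/ms).
#' @param hv_coefs post-spike voltage filter per hv-basis bin (mV).
#' @param vth static threshold (mV).
#' @param hth_coefs post-spike threshold filter per hth-basis bin (mV).
#' @param delta_v voltage scale of the exponential nonlinearity (mV), > 0.
#' @param bases list of three [basis_spec()]s (`k`, `hv`, `hth`).
#' @param cell_id optional identifier.
#' @return An `srm_params` object.
#' @export
srm_params <- function(vb, k_coefs, hv_coefs, vth, hth_coefs, delta_v,
                       bases = default_bases(), cell_id = NULL) {
  stopifnot(is.finite(delta_v), delta_v > 0,
            length(k_coefs) == bases$k$n_bins,
            length(hv_coefs) == bases$hv$n_bins,
            length(hth_coefs) == bases$hth$n_bins)
  structure(list(vb = vb, k_coefs = as.numeric(k_coefs),
                 hv_coefs = as.numeric(hv_coefs), vth = vth,
                 hth_coefs = as.numeric(hth_coefs), delta_v = delta_v,
                 bases = bases, cell_id = cell_id),
            class = "srm_params")
}

#' Input resistance implied by the membrane filter
#'
#' Area under k(t): `sum(k_coefs) * width` in mV/pA (GOhm), returned in MOhm.
#' @param p an [srm_params()].
#' @return Resistance in MOhm.
#' @export
filter_resistance <- function(p) {
  1000 * sum(p$k_coefs) * p$bases$k$width
}

#' Discretize the membrane filter on a grid
#'
#' Per-sample convolution weights `k(u*dt) * dt` for lags `u = 0, 1, ...`
#' covering the basis support.
#' @param p an [srm_params()].
#' @param dt grid step (ms).
#' @return Numeric vector of length `support/dt`.
#' @export
discretize_k <- function(p, dt) {
  K <- as.integer(round(p$bases$k$support / dt))
  u <- (0:(K - 1)) * dt
  eval_filter(p$k_coefs, p$bases$k, u) * dt
}

# post-spike kernels sampled at lags u*dt for u >= 1 (a spike at bin t acts
# from bin t+1 onward); index [u] of the result is the value at lag u*dt
discretize_h <- function(coefs, basis, dt) {
  K <- as.integer(round(basis$support / dt))
  u <- (1:K) * dt
  eval_filter(coefs, basis, u)
}

# causal convolution sum_{u} kd[u+1] * x[t-u]; FFT for long inputs
causal_conv <- function(x, kd) {
  n <- length(x); K <- length(kd)
  if (as.double(n) * K < 5e7) return(as.numeric(causal_conv_cpp(x, kd)))
  m <- stats::nextn(n + K - 1L, 2)
  xf <- stats::fft(c(x, numeric(m - n)))
  kf <- stats::fft(c(kd, numeric(m - K)))
  out <- Re(stats::fft(xf * kf, inverse = TRUE)) / m
  out[seq_len(n)]
}

spike_bins_of <- function(s, dt, n) {
  b <- as.integer(round(s$times / dt)) + 1L
  b[b >= 1L & b <= n]
}

#' Subthreshold membrane potential of the SRM
#'
#' \eqn{v(t) = v_b + \int_0^t k(u) i(t-u) du + \sum_{t_s} h_v(t - t_s)}:
#' bias plus the causal convolution of the stimulus with the membrane filter,
#' plus a post-spike membrane kick after every spike. Deterministic given the
#' stimulus and spike times.
#'
#' @param p an [srm_params()].
#' @param stim a [stimulus_trace()] in pA.
#' @param spikes a [spike_train()] (may be empty).
#' @return Numeric voltage trace (mV) on the stimulus grid.
#' @export
subthreshold_voltage <- function(p, stim, spikes = spike_train(numeric(0), stim$n * stim$dt)) {
  stopifnot(inherits(p, "srm_params"), inherits(stim, "stimulus_trace"))
  if (abs(spikes$duration - stim$n * stim$dt) > stim$dt / 2)
    stop("spike train and stimulus durations disagree")
  dt <- stim$dt
  v <- p$vb + causal_conv(stim$values, discretize_k(p, dt))
  if (n_spikes(spikes)) {
    hv <- discretize_h(p$hv_coefs, p$bases$hv, dt)
    v <- v + as.numeric(spike_history_cpp(spike_bins_of(spikes, dt, stim$n), hv, stim$n))
  }
  v
}

#' Conditional intensity of the SRM
#'
#' \eqn{\lambda(t) = \exp\{(v(t) - v_{th} - \sum_{t_s} h_{th}(t-t_s)) /
#' \Delta v\}} in 1/ms, so that \eqn{\lambda(t)\Delta t} is dimensionless.
#' The exponent is clipped at `clip` (overflow guard); the number of clipped
#' bins is reported as an attribute.
#'
#' @param p an [srm_params()].
#' @param v voltage trace (mV) as from [subthreshold_voltage()].
#' @param spikes a [spike_train()].
#' @param dt grid step (ms).
#' @param clip exponent cap.
#' @return Numeric vector \eqn{\lambda(t)} (1/ms), attribute `n_clipped`.
#' @export
conditional_intensity <- function(p, v, spikes, dt, clip = 20) {
  n <- length(v)
  ex <- (v - p$vth) / p$delta_v
  if (n_spikes(spikes)) {
    hth <- discretize_h(p$hth_coefs, p$bases$hth, dt)
    ex <- ex - as.numeric(spike_history_cpp(spike_bins_of(spikes, dt, n), hth, n)) / p$delta_v
  }
  ncl <- sum(ex > clip)
  if (ncl > 0) warning(sprintf("conditional intensity exponent clipped at %d bins", ncl))
  lam <- exp(pmin(ex, clip))
  attr(lam, "n_clipped") <- ncl
  lam
}

#' Recording container
#'
#' One trial: the injected current, the model (or measured) voltage, and the
#' spike train, on a common grid.
#' @param stimulus [stimulus_trace()] in pA.
#' @param voltage numeric voltage trace (mV) or NULL.
#' @param spikes [spike_train()].
#' @param cell_id,trial_id identifiers.
#' @return A `recording` object with `dt` taken from the stimulus.
#' @export
recording <- function(stimulus, voltage, spikes, cell_id = NULL, trial_id = NULL) {
  stopifnot(inherits(stimulus, "stimulus_trace"), inherits(spikes, "spike_train"))
  if (!is.null(voltage) && length(voltage) != stimulus$n)
    stop("voltage and stimulus lengths disagree")
  structure(list(stimulus = stimulus, voltage = voltage, spikes = spikes,
                 cell_id = cell_id, trial_id = trial_id, dt = stimulus$dt),
            class = "recording")
}

#' Simulate the SRM response to a current
#'
#' Iterates over time bins; at each bin a spike is drawn with probability
#' \eqn{1 - \exp(-\lambda(t)\Delta t)}; each spike appends its h_v and h_th
#' contributions to all subsequent bins (starting at the next bin).
#'
#' @param p an [srm_params()].
#' @param stim a [stimulus_trace()] in pA.
#' @param seed optional seed (bit-reproducible output for a fixed seed).
#' @param clip exponent cap (see [conditional_intensity()]).
#' @return A [recording()]; `$n_clipped` on the recording counts clip events.
#' @export
simulate_srm <- function(p, stim, seed = NULL, clip = 20) {
  stopifnot(inherits(p, "srm_params"), inherits(stim, "stimulus_trace"))
  if (!is.null(seed)) set.seed(seed)
  dt <- stim$dt
  v_stim <- p$vb + causal_conv(stim$values, discretize_k(p, dt))
  base <- (v_stim - p$vth) / p$delta_v
  hv <- discretize_h(p$hv_coefs, p$bases$hv, dt)
  hth <- discretize_h(p$hth_coefs, p$bases$hth, dt)
  sim <- srm_simulate_cpp(base, hv / p$delta_v, hth / p$delta_v, dt, clip)
  voltage <- v_stim + p$delta_v * sim$hv_acc
  spikes <- spike_train((sim$spike_bins - 1L) * dt, stim$n * dt)
  rec <- recording(stim, voltage, spikes, cell_id = p$cell_id)
  rec$n_clipped <- sim$n_clipped
  rec
}

#' Serialize SRM parameters to JSON (and back)
#'
#' @param p an [srm_params()].
#' @param path file path.
#' @return `read_srm_json` returns an [srm_params()].
#' @export
write_srm_json <- function(p, path) {
  x <- unclass(p)
  x$bases <- lapply(x$bases, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_srm_json
#' @export
read_srm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bases <- lapply(x$bases, function(b) basis_spec(b$n_bins, b$width, b$start))
  srm_params(x$vb, x$k_coefs, x$hv_coefs, x$vth, x$hth_coefs, x$delta_v,
             bases = bases, cell_id = x$cell_id)
}
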