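#' Coincidence window specification
#'
#' Rectangular coincidence kernel of width `window` (ms): two spikes are
#' coincident when they fall within `window / 2` of each other (closed
#' boundary: separation exactly `window / 2` counts). The study uses 8 ms,
#' comparable to the duration of an action potential.
#'
#' @param window full window width Delta in ms.
#' @return A `coincidence_spec` list.
#' @export
coincidence_spec <- function(window = 8) {
  if (!is.finite(window) || window <= 0) stop("window must be positive")
  structure(list(window = window), class = "coincidence_spec")
}

#' Count coincident spikes between two trains
#'
#' Number of spike pairs \eqn{(t_a, t_b)} with \eqn{|t_a - t_b| \le \Delta/2}.
#' Symmetric in its arguments. For trains whose inter-spike intervals all
#' exceed \eqn{\Delta/2}, the self-coincidence `count_coincidences(s, s, spec)`
#' equals the spike count `n_spikes(s)`.
#'
#' @param a,b [spike_train()] objects of equal duration.
#' @param spec a [coincidence_spec()].
#' @return Integer count of coincident pairs.
#' @export
count_coincidences <- function(a, b, spec = coincidence_spec()) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"),
            inherits(spec, "coincidence_spec"))
  if (abs(a$duration - b$duration) > 1e-9)
    stop("trains must share one duration")
  ta <- a$times; tb <- b$times
  if (!length(ta) || !length(tb)) return(0L)
  half <- spec$window / 2
  # tb is sorted: count tb in [t - half, t + half] per spike of a
  lo <- findInterval(ta - half, tb, left.open = TRUE)   # tb strictly below t-half
  hi <- findInterval(ta + half, tb)                     # tb <= t+half
  as.integer(sum(hi - lo))
}

total_pair_coincidences <- function(A, B, spec) {
  s <- 0L
  for (a in A$trains) for (b in B$trains)
    s <- s + count_coincidences(a, b, spec)
  s
}

#' Coincidence ratio between two trial sets
#'
#' \deqn{C(S, S') = \frac{\frac{1}{M^2}\sum_{i,j} c(s_i, s'_j)}
#'   {(N(S) + N(S'))/2}}
#' the average number of coincidences between the sets, normalized by the
#' average number of spikes in their trains.
#'
#' @param A,B [trial_set()] objects with equal trial counts.
#' @param spec a [coincidence_spec()].
#' @return The coincidence ratio (0 when there are coincidences nowhere).
#' @export
coincidence_ratio <- function(A, B, spec = coincidence_spec()) {
  stopifnot(inherits(A, "trial_set"), inherits(B, "trial_set"))
  if (A$M != B$M) stop("trial sets must have equal trial counts")
  denom <- (mean_spike_count(A) + mean_spike_count(B)) / 2
  if (denom == 0) stop("both trial sets are empty of spikes; ratio undefined")
  (total_pair_coincidences(A, B, spec) / A$M^2) / denom
}

#' Within-set reliability
#'
#' \deqn{R(S) = \frac{1}{M(M-1)}\sum_{i \ne j} c(s_i, s_j) \big/ N(S)}
#' the average number of coincidences between different trials, normalized by
#' the average spike count; quantifies response reproducibility across trials.
#' For M independent Poisson trains of rate \eqn{\lambda}, the expected
#' reliability is the chance level \eqn{\lambda\Delta}.
#'
#' @param A a [trial_set()] with at least two trials.
#' @param spec a [coincidence_spec()].
#' @return Reliability in `[0, 1 + eps]` (slightly above 1 is possible when a
#'   spike has several partners within one window).
#' @export
reliability <- function(A, spec = coincidence_spec()) {
  stopifnot(inherits(A, "trial_set"))
  M <- A$M
  if (M < 2) stop("reliability needs at least two trials")
  N <- mean_spike_count(A)
  if (N == 0) stop("empty trial set; reliability undefined")
  tot <- 0L
  for (i in seq_len(M - 1)) for (j in (i + 1):M)
    tot <- tot + count_coincidences(A$trains[[i]], A$trains[[j]], spec)
  (2 * tot / (M * (M - 1))) / N
}

#' Md similarity between two trial sets
#'
#' Coincidence-based degree of similarity that accounts for the internal
#' reliability of each set:
#' \deqn{M_d(S, S') = \frac{\frac{1}{M^2}\sum_{i,j} c(s_i, s'_j)}
#'   {(N(S)R(S) + N(S')R(S'))/2}.}
#' Equals 1 when `A` and `B` are the same set.
#'
#' @param A,B [trial_set()] objects, each with at least two trials.
#' @param spec a [coincidence_spec()].
#' @return The Md similarity.
#' @export
md_similarity <- function(A, B, spec = coincidence_spec()) {
  stopifnot(inherits(A, "trial_set"), inherits(B, "trial_set"))
  if (A$M < 2 || B$M < 2) stop("Md needs at least two trials per set")
  denom <- (mean_spike_count(A) * reliability(A, spec) +
            mean_spike_count(B) * reliability(B, spec)) / 2
  if (denom == 0) stop("zero denominator: both reliabilities vanish")
  (total_pair_coincidences(A, B, spec) / (A$M * B$M)) / denom
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate: spike counts on the `dt` grid, smoothed with a
#' rectangular sliding window and divided by the locally valid window length
#' (edge-corrected), in spikes/s. Conserves the total count:
#' `sum(rate) * dt / 1000 * M` equals the number of spikes.
#'
#' @param A a [trial_set()].
#' @param window_ms boxcar width in ms (default 40).
#' @param dt grid step in ms.
#' @return A list with `time_ms`, `rate_hz`, `window_ms`, `dt`.
#' @export
psth <- function(A, window_ms = 40, dt = 1) {
  stopifnot(inherits(A, "trial_set"))
  if (window_ms < dt) stop("window must be >= dt")
  n <- as.integer(ceiling(A$duration / dt))
  counts <- numeric(n)
  for (s in A$trains) {
    idx <- pmin(floor(s$times / dt) + 1L, n)
    tab <- tabulate(idx, nbins = n)
    counts <- counts + tab
  }
  counts <- counts / A$M
  w <- max(1L, as.integer(round(window_ms / dt)))
  half <- (w - 1L) %/% 2L
  i <- seq_len(n)
  # each spike's mass is spread over the bins whose window covers it; dividing
  # by the per-source coverage makes the smoothing mass-conserving at edges
  cover <- pmin(n, i + half) - pmax(1L, i - (w - 1L - half)) + 1L
  cs <- c(0, cumsum(counts / cover))
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + (w - 1L - half))
  sm <- cs[hi + 1L] - cs[lo]
  rate <- 1000 * sm / dt
  list(time_ms = (seq_len(n) - 0.5) * dt, rate_hz = rate,
       window_ms = window_ms, dt = dt)
}

#' Cross-correlation between a stimulus and a PSTH
#'
#' Pearson correlation of the mean-subtracted overlapping segments at each
#' integer-lag shift. Positive lag means the response lags the stimulus.
#'
#' @param stim numeric stimulus vector on the PSTH grid.
#' @param rate numeric PSTH vector of the same length.
#' @param dt grid step (ms).
#' @param max_lag_ms lag range (default +-200 ms).
#' @return List with `lag_ms`, `correlation`, `peak_lag_ms`, `peak_value`.
#' @export
stim_psth_xcorr <- function(stim, rate, dt = 1, max_lag_ms = 200) {
  if (length(stim) != length(rate)) stop("stimulus and PSTH must have equal length")
  if (stats::sd(stim) == 0 || stats::sd(rate) == 0)
    stop("zero-variance input; correlation undefined")
  n <- length(stim)
  L <- min(n - 2L, as.integer(round(max_lag_ms / dt)))
  lags <- (-L):L
  cors <- vapply(lags, function(l) {
    if (l >= 0) stats::cor(stim[1:(n - l)], rate[(1 + l):n])
    else        stats::cor(stim[(1 - l):n], rate[1:(n + l)])
  }, numeric(1))
  k <- which.max(cors)
  list(lag_ms = lags * dt, correlation = cors,
       peak_lag_ms = lags[k] * dt, peak_value = cors[k])
}

#' Shuffle spike times within trials
#'
#' Control used against chance coincidences: keeps the per-trial spike counts
#' and redraws the times uniformly on `[0, duration)`.
#'
#' @param A a [trial_set()].
#' @param seed optional seed.
#' @return A [trial_set()] of shuffled trains.
#' @export
shuffle_times <- function(A, seed = NULL) {
  stopifnot(inherits(A, "trial_set"))
  if (!is.null(seed)) set.seed(seed)
  trains <- lapply(A$trains, function(s) {
    k <- n_spikes(s)
    ts <- sort(stats::runif(k, 0, s$duration))
    while (k > 1 && any(diff(ts) == 0))  # measure-zero; keep strict ordering
      ts <- sort(stats::runif(k, 0, s$duration))
    spike_train(ts, s$duration)
  })
  trial_set(trains, stimulus_id = A$stimulus_id)
}

#' Passive membrane properties from a hyperpolarizing current step
#'
#' Fits \eqn{v(t) = v_0 + \Delta V (1 - e^{-t/\tau_m})} to the voltage
#' deflection following a small hyperpolarizing step and reports the input
#' resistance \eqn{R_{in} = \Delta V / I_{step}} and membrane time constant.
#'
#' @param voltage numeric voltage trace (mV).
#' @param dt sample step (ms).
#' @param step_onset_ms time at which the current step turns on.
#' @param step_pa step amplitude in pA (negative for hyperpolarizing).
#' @param fit_window_ms length of trace after onset used for the fit.
#' @return A `passive_fit` list: `r_in` (MOhm), `tau_m` (ms), `delta_v` (mV),
#'   `v0` (mV), `fit_rmse` (mV).
#' @export
fit_passive <- function(voltage, dt, step_onset_ms, step_pa,
                        fit_window_ms = 200) {
  if (!is.finite(step_pa) || step_pa == 0) stop("step amplitude must be nonzero")
  i0 <- as.integer(round(step_onset_ms / dt)) + 1L
  i1 <- min(length(voltage), i0 + as.integer(round(fit_window_ms / dt)))
  if (i1 - i0 < 10) stop("fit window too short")
  t <- (seq(i0, i1) - i0) * dt
  v <- voltage[i0:i1]
  v0_start <- v[1]
  dv_start <- v[length(v)] - v[1]
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ v0 + dv * (1 - exp(-t / tau)),
                      start = list(v0 = v0_start, dv = dv_start,
                                   tau = fit_window_ms / 5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("passive fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  tau_m <- unname(cf["tau"]); dv <- unname(cf["dv"])
  if (tau_m <= 0) stop("passive fit produced non-positive tau")
  r_in <- dv / step_pa * 1000  # mV/pA = GOhm -> MOhm
  if (r_in <= 0) stop("passive fit produced non-positive input resistance")
  structure(list(r_in = r_in, tau_m = tau_m, delta_v = dv, v0 = unname(cf["v0"]),
                 fit_rmse = sqrt(mean(stats::resid(fit)^2))),
            class = "passive_fit")
}

#' Detect spikes from a voltage trace
#'
#' Upward threshold crossings with a refractory lockout; the spike time is the
#' crossing time. Threshold 0 mV and 2 ms refractory period by default.
#'
#' @param voltage numeric voltage trace (mV).
#' @param dt sample step (ms).
#' @param threshold_mv detection threshold (mV).
#' @param refractory_ms minimum separation between detected spikes.
#' @return A [spike_train()].
#' @export
detect_spikes <- function(voltage, dt, threshold_mv = 0, refractory_ms = 2) {
  n <- length(voltage)
  up <- which(voltage[-1] >= threshold_mv & voltage[-n] < threshold_mv) + 1L
  times <- (up - 1L) * dt
  if (length(times) > 1) {
    keep <- c(TRUE, rep(FALSE, length(times) - 1L))
    last <- times[1]
    for (i in 2:length(times)) {
      if (times[i] - last >= refractory_ms) { keep[i] <- TRUE; last <- times[i] }
    }
    times <- times[keep]
  }
  spike_train(times, n * dt)
}
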