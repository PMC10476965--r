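#' Stimulus trace container
#'
#' A discretized time series of injected current, either in normalized units
#' (the unit-variance process \eqn{\eta(t)}) or in pA after scaling.
#'
#' @param values numeric vector of samples.
#' @param dt time step in ms.
#' @param units character, `"normalized"` or `"pA"`.
#' @param meta optional named list of provenance metadata (seed, spec, ...).
#' @return An object of class `stimulus_trace` with fields `values`, `dt`,
#'   `n`, `units`, `meta`.
#' @export
stimulus_trace <- function(values, dt, units = "normalized", meta = list()) {
  stopifnot(is.numeric(values), is.numeric(dt), length(dt) == 1L, dt > 0)
  if (!all(is.finite(values))) stop("stimulus values must be finite")
  structure(
    list(values = as.numeric(values), dt = dt, n = length(values),
         units = units, meta = meta),
    class = "stimulus_trace"
  )
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("<stimulus_trace> %d samples, dt = %g ms (%.3g s), units = %s\n",
              x$n, x$dt, x$n * x$dt / 1000, x$units))
  invisible(x)
}

#' Ornstein-Uhlenbeck stimulus specification
#'
#' Parameters of the zero-mean, unit-variance OU process with correlation time
#' `tau`, discretized on a grid of step `dt` as an AR(1) recursion with
#' coefficient \eqn{\beta = e^{-\Delta t/\tau}}.
#'
#' @param tau correlation time constant (ms); the study's stimuli use 3 ms.
#' @param dt time step (ms); defaults to 0.1 ms (10 kHz acquisition).
#' @param duration total duration (ms).
#' @param seed optional integer seed.
#' @return An `ou_spec` list.
#' @export
ou_spec <- function(tau = 3, dt = 0.1, duration = 10000, seed = NULL) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be finite and positive")
  if (!is.finite(dt) || dt <= 0) stop("dt must be finite and positive")
  if (!is.finite(duration) || duration < dt) stop("duration must be >= dt")
  structure(list(tau = tau, dt = dt, duration = duration, seed = seed,
                 beta = exp(-dt / tau)),
            class = "ou_spec")
}

n_samples <- function(spec) as.integer(round(spec$duration / spec$dt))

#' Sample a discretized Ornstein-Uhlenbeck stimulus
#'
#' Iterates \eqn{\eta(t+\Delta t) = \eta(t)\beta + \sqrt{1-\beta^2}\,
#' \mathcal{N}(0,1)} with \eqn{\eta(0) \sim \mathcal{N}(0,1)}, so the sampled
#' process is stationary with mean 0 and variance 1 at every time.
#'
#' @param spec an [ou_spec()].
#' @param innovations optional numeric vector of standard-normal innovations
#'   (length `n_samples - 1`), used instead of fresh draws; exposed so the
#'   recursion can be driven deterministically.
#' @param x0 optional fixed starting value (default: a fresh N(0,1) draw).
#' @return A [stimulus_trace()] in normalized units.
#' @export
sample_ou <- function(spec, innovations = NULL, x0 = NULL) {
  stopifnot(inherits(spec, "ou_spec"))
  n <- n_samples(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  beta <- spec$beta
  if (is.null(x0)) x0 <- stats::rnorm(1)
  if (n == 1L) return(stimulus_trace(x0, spec$dt, meta = list(spec = unclass(spec))))
  eps <- if (is.null(innovations)) stats::rnorm(n - 1L) else {
    if (length(innovations) != n - 1L) stop("need n - 1 innovations")
    innovations
  }
  sd_innov <- sqrt(1 - beta^2)
  # AR(1) recursion, vectorized: x_t = beta * x_{t-1} + sd * eps_t
  x <- stats::filter(c(x0, sd_innov * eps), beta, method = "recursive",
                     init = 0)
  # filter() treats x0 as an innovation of the first step, which is exactly
  # the stationary start: x_1 = x0, x_t = beta x_{t-1} + sd eps_t.
  stimulus_trace(as.numeric(x), spec$dt,
                 meta = list(spec = unclass(spec)))
}

#' Theta-modulated stimulus specification
#'
#' Gaussian stimulus with autocovariance
#' \eqn{\rho(u) = \sigma^2 \cos(2\pi f u)\, e^{-u/\tau}} (u in ms, f in Hz),
#' sampled by Cholesky factorization of the dense covariance matrix.
#'
#' @param f oscillation frequency (Hz); the study uses 8 Hz.
#' @param tau envelope decay time (ms); the study uses 100 ms.
#' @param sigma2 stationary variance.
#' @param dt time step (ms).
#' @param duration total duration (ms).
#' @param seed optional seed.
#' @param mu mean offset added after sampling.
#' @param max_n guard on the dense covariance size.
#' @return A `theta_spec` list.
#' @export
theta_spec <- function(f = 8, tau = 100, sigma2 = 1, dt = 1, duration = 10000,
                       seed = NULL, mu = 0, max_n = 20000L) {
  if (!is.finite(f) || f < 0) stop("f must be >= 0")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  structure(list(f = f, tau = tau, sigma2 = sigma2, dt = dt,
                 duration = duration, seed = seed, mu = mu, max_n = max_n),
            class = "theta_spec")
}

#' Analytic autocovariance of the theta stimulus
#'
#' @param spec a [theta_spec()].
#' @param u vector of non-negative lags (ms).
#' @return `sigma2 * cos(2*pi*f*u) * exp(-u/tau)`.
#' @export
theta_autocov <- function(spec, u) {
  spec$sigma2 * cos(2 * pi * spec$f * u / 1000) * exp(-abs(u) / spec$tau)
}

#' Sample theta-modulated stimuli by dense Cholesky factorization
#'
#' Builds \eqn{C_{ij} = \rho((i-j)\Delta t)}, factors \eqn{C = LL^T} (adding a
#' small diagonal jitter if the factorization fails numerically), and returns
#' \eqn{L\epsilon + \mu} with iid standard normal \eqn{\epsilon}. The factor
#' is computed once even when several traces are requested.
#'
#' @param spec a [theta_spec()].
#' @param n_traces number of independent traces to draw.
#' @return A single [stimulus_trace()] if `n_traces == 1`, otherwise a list of
#'   traces. Jitter used (if any) is recorded in `meta$jitter`.
#' @export
sample_theta <- function(spec, n_traces = 1L) {
  stopifnot(inherits(spec, "theta_spec"))
  n <- n_samples(spec)
  if (n > spec$max_n)
    stop(sprintf("dense theta covariance would be %d x %d; raise max_n if intended", n, n))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  u <- (0:(n - 1L)) * spec$dt
  C <- stats::toeplitz(theta_autocov(spec, u))
  jitter <- 0
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) {
    jitter <- 1e-10 * spec$sigma2
    L <- tryCatch(chol(C + diag(jitter, n)), error = function(e) NULL)
    k <- 0
    while (is.null(L) && k < 6) {
      jitter <- jitter * 100
      L <- tryCatch(chol(C + diag(jitter, n)), error = function(e) NULL)
      k <- k + 1
    }
    if (is.null(L))
      stop("theta covariance not positive definite even after jitter ",
           format(jitter))
  }
  eps <- matrix(stats::rnorm(n * n_traces), n, n_traces)
  X <- crossprod(L, eps) + spec$mu   # chol() returns the upper factor
  traces <- lapply(seq_len(n_traces), function(j)
    stimulus_trace(X[, j], spec$dt,
                   meta = list(spec = unclass(spec), jitter = jitter)))
  if (n_traces == 1L) traces[[1L]] else traces
}

#' Spectral peak of a set of stimulus traces
#'
#' Averages the periodograms of the traces and locates the power maximum.
#' Because a cosine-modulated exponential autocovariance produces a broad
#' (Lorentzian) spectral peak, the raw argmax of a finite average jitters by
#' several bins; the default refinement fits a mirrored Lorentzian pair plus
#' a flat floor around the maximum and reports the peak of the fitted curve.
#'
#' @param traces a list of [stimulus_trace()]s on a common grid.
#' @param method `"lorentzian"` (model refinement, default) or `"argmax"`
#'   (raw maximal bin).
#' @param window_hz half-width (Hz) of the fit window around the maximum.
#' @return List `peak_hz`, `freq_hz`, `power` (averaged periodogram).
#' @export
spectral_peak <- function(traces, method = c("lorentzian", "argmax"),
                          window_hz = 8) {
  method <- match.arg(method)
  if (inherits(traces, "stimulus_trace")) traces <- list(traces)
  n <- traces[[1]]$n; dt <- traces[[1]]$dt
  pow <- Reduce(`+`, lapply(traces, function(tr) {
    x <- tr$values - mean(tr$values)
    Mod(stats::fft(x))^2
  })) / length(traces)
  freq <- (0:(n - 1)) / (n * dt * 1e-3)  # Hz
  half <- 2:(n %/% 2)
  f <- freq[half]; p <- pow[half]
  k <- which.max(p)
  out <- list(peak_hz = f[k], freq_hz = f, power = p)
  if (method == "argmax") return(out)
  win <- abs(f - f[k]) <= window_hz
  fw <- f[win]; pw <- p[win]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      pw ~ A * (g^2 / ((fw - f0)^2 + g^2) + g^2 / ((fw + f0)^2 + g^2)) + c0,
      start = list(A = max(pw), g = window_hz / 5, f0 = f[k], c0 = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    fg <- seq(max(f[1], cf[["f0"]] - 3), cf[["f0"]] + 3, by = 0.001)
    Sg <- cf[["A"]] * (cf[["g"]]^2 / ((fg - cf[["f0"]])^2 + cf[["g"]]^2) +
                       cf[["g"]]^2 / ((fg + cf[["f0"]])^2 + cf[["g"]]^2)) + cf[["c0"]]
    cand <- fg[which.max(Sg)]
    if (is.finite(cand) && abs(cand - f[k]) <= window_hz) out$peak_hz <- cand
  }
  out
}

#' Correlated stimulus pair specification
#'
#' @param rho instantaneous cross-correlation of the pair, in `[0, 1)`.
#'   Named separation levels of the discrimination task: low = 0.9997,
#'   medium = 0.999, high = 0.99.
#' @param base an [ou_spec()] shared by both members.
#' @return A `pair_spec` list.
#' @export
pair_spec <- function(rho, base = ou_spec()) {
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)")
  structure(list(rho = rho, base = base), class = "pair_spec")
}

#' Separation levels of the pattern-discrimination task
#'
#' @param level one of `"low"`, `"medium"`, `"high"`.
#' @return The corresponding pair correlation rho.
#' @export
separation_rho <- function(level = c("high", "medium", "low")) {
  level <- match.arg(level)
  c(high = 0.99, medium = 0.999, low = 0.9997)[[level]]
}

#' Sample a pair of correlated Ornstein-Uhlenbeck stimuli
#'
#' Bivariate AR(1) recursion whose innovations have covariance
#' \eqn{K = [[1,\rho],[\rho,1]]}; each marginal is a stationary unit-variance
#' OU process with the base time constant, and the instantaneous correlation
#' between members is \eqn{\rho}.
#'
#' @param spec a [pair_spec()].
#' @return A list of two [stimulus_trace()] objects.
#' @export
sample_pair <- function(spec) {
  stopifnot(inherits(spec, "pair_spec"))
  base <- spec$base
  n <- n_samples(base)
  if (!is.null(base$seed)) set.seed(base$seed)
  rho <- spec$rho
  beta <- base$beta
  # chol(K): correlate two standard-normal streams
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  e1 <- z1
  e2 <- rho * z1 + sqrt(1 - rho^2) * z2
  sd_innov <- sqrt(1 - beta^2)
  ar1 <- function(e) {
    x <- stats::filter(c(e[1], sd_innov * e[-1]), beta,
                       method = "recursive", init = 0)
    as.numeric(x)
  }
  meta <- list(spec = list(rho = rho, base = unclass(base)))
  list(stimulus_trace(ar1(e1), base$dt, meta = meta),
       stimulus_trace(ar1(e2), base$dt, meta = meta))
}

#' Current scaling specification
#'
#' Injected currents take the form \eqn{i(t) = \sigma\eta(t) + \mu}, where
#' `mu` sets the mean current and `sigma` the fluctuation amplitude (both pA).
#'
#' @param mu mean current (pA).
#' @param sigma fluctuation amplitude (pA), non-negative.
#' @return A `scaling_spec` list.
#' @export
scaling_spec <- function(mu, sigma) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  structure(list(mu = mu, sigma = sigma), class = "scaling_spec")
}

#' Scale a normalized stimulus into a current in pA
#'
#' @param trace a [stimulus_trace()].
#' @param s a [scaling_spec()].
#' @return A [stimulus_trace()] with values `sigma * eta + mu` in pA.
#' @export
scale_stimulus <- function(trace, s) {
  stopifnot(inherits(trace, "stimulus_trace"), inherits(s, "scaling_spec"))
  stimulus_trace(s$sigma * trace$values + s$mu, trace$dt, units = "pA",
                 meta = c(trace$meta, list(scaling = unclass(s))))
}

#' Noise-corruption specification
#'
#' Corruption level \eqn{\nu \in [0,1)} of the variance-preserving mixture
#' used in the discrimination task's noise sweep (levels 0.25/0.5/0.75/0.9).
#'
#' @param level corruption fraction in `[0, 1)`.
#' @param seed optional seed for the corrupting draw.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(level, seed = NULL) {
  if (!is.finite(level) || level < 0 || level >= 1)
    stop("noise level must lie in [0, 1)")
  structure(list(level = level, seed = seed), class = "noise_spec")
}

#' Corrupt a normalized stimulus with independent OU noise
#'
#' Variance-preserving mixture \eqn{\sqrt{1-\nu^2}\,\eta + \nu\,\xi} with
#' \eqn{\xi} an independent OU draw of the same correlation time, so the
#' corrupted stimulus stays in the prior's stationary distribution and its
#' correlation with the original is \eqn{\sqrt{1-\nu^2}}.
#'
#' @param trace a normalized-unit [stimulus_trace()].
#' @param noise a [noise_spec()].
#' @param ou an [ou_spec()] for the corrupting process; duration/dt must match
#'   the trace.
#' @return A [stimulus_trace()]; `meta$noise_level` records nu.
#' @export
corrupt_stimulus <- function(trace, noise, ou) {
  stopifnot(inherits(trace, "stimulus_trace"), inherits(noise, "noise_spec"),
            inherits(ou, "ou_spec"))
  nu <- noise$level
  if (nu == 0) {
    out <- trace
    out$meta$noise_level <- 0
    return(out)
  }
  ou2 <- ou_spec(tau = ou$tau, dt = trace$dt, duration = trace$n * trace$dt,
                 seed = noise$seed)
  xi <- sample_ou(ou2)
  stimulus_trace(sqrt(1 - nu^2) * trace$values + nu * xi$values, trace$dt,
                 units = trace$units,
                 meta = c(trace$meta, list(noise_level = nu)))
}

#' Write / read a stimulus trace as two-column CSV
#'
#' Plain-text round-trip: columns `time_ms`, `value`; `dt` and units are
#' recovered from the time column and a header comment.
#'
#' @param trace a [stimulus_trace()].
#' @param path file path.
#' @return `read_stimulus_csv` returns a [stimulus_trace()].
#' @export
write_stimulus_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units=%s dt=%.17g", trace$units, trace$dt), con)
  utils::write.table(
    data.frame(time_ms = (seq_len(trace$n) - 1) * trace$dt,
               value = trace$values),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  units <- sub(".*units=(\\S+).*", "\\1", hdr)
  dt <- as.numeric(sub(".*dt=(\\S+).*", "\\1", hdr))
  df <- utils::read.csv(path, comment.char = "#")
  stimulus_trace(df$value, dt, units = units)
}
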