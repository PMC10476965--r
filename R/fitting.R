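#' Fitting configuration
#'
#' @param alpha_grid candidate smoothness penalties for the threshold filter;
#'   the value with the largest validation log-likelihood is kept.
#' @param newton_tol Newton stopping tolerance on the max absolute gradient.
#' @param max_iter maximum Newton iterations.
#' @param postspike_mask_ms voltage mask after every spike for the
#'   subthreshold stage (ms).
#' @param delta_v0 initial voltage scale for the threshold stage (mV).
#' @return A `fit_config` list.
#' @export
fit_config <- function(alpha_grid = c(0, 0.1, 1, 10, 100, 1000),
                       newton_tol = 1e-6, max_iter = 100,
                       postspike_mask_ms = 25, delta_v0 = 1) {
  stopifnot(all(alpha_grid >= 0), newton_tol > 0, max_iter >= 1)
  structure(list(alpha_grid = alpha_grid, newton_tol = newton_tol,
                 max_iter = max_iter, postspike_mask_ms = postspike_mask_ms,
                 delta_v0 = delta_v0),
            class = "fit_config")
}

# sample-lag range [lo, hi) of basis bin j on a grid of step dt,
# with post-spike kernels starting at lag 1 (see the simulator convention)
bin_lag_range <- function(basis, j, dt, postspike = FALSE) {
  lo <- as.integer(round((basis$start + (j - 1) * basis$width) / dt))
  hi <- as.integer(round((basis$start + j * basis$width) / dt))
  if (postspike) lo <- max(lo, 1L)
  c(lo, hi)
}

#' Build the regression design matrix of the subthreshold stage
#'
#' Rows are time bins; columns are the intercept, the J convolutions of the
#' stimulus with the membrane-filter basis functions, and the L post-spike
#' sums of the voltage-filter basis functions. Rows falling within
#' `mask_ms` after any spike are flagged (not dropped), so the unmasked
#' matrix can be reused by the threshold stage.
#'
#' @param stim a [stimulus_trace()] in pA.
#' @param spikes a [spike_train()].
#' @param bases list with [basis_spec()]s `k` and `hv` (and `hth`, unused here).
#' @param mask_ms post-spike mask length (ms).
#' @return List with `X` (matrix), `mask` (logical, TRUE = masked), `dt`,
#'   `bases`, `spike_bins`.
#' @export
build_design <- function(stim, spikes, bases = default_bases(), mask_ms = 25) {
  stopifnot(inherits(stim, "stimulus_trace"), inherits(spikes, "spike_train"))
  dt <- stim$dt
  n <- stim$n
  if (bases$k$support >= n * dt || bases$hv$support >= n * dt)
    stop("basis support exceeds trace length")
  J <- bases$k$n_bins; L <- bases$hv$n_bins
  X <- matrix(0, n, 1L + J + L)
  X[, 1L] <- 1
  # stimulus columns by cumulative sums: sum_{u in bin j} i(t - u)
  cs <- c(0, cumsum(stim$values))  # cs[m+1] = sum of first m samples
  tt <- seq_len(n)
  for (j in seq_len(J)) {
    r <- bin_lag_range(bases$k, j, dt)
    hi_idx <- pmax(tt - r[1L], 0L)        # number of samples up to lag lo
    lo_idx <- pmax(tt - r[2L] + 1L, 0L)   # ... up to lag hi - 1
    X[, 1L + j] <- cs[hi_idx + 1L] - cs[pmax(lo_idx - 1L, 0L) + 1L]
  }
  sb <- spike_bins_of(spikes, dt, n)
  for (l in seq_len(L)) {
    r <- bin_lag_range(bases$hv, l, dt, postspike = TRUE)
    acc <- numeric(n + 1L)
    for (b in sb) {
      lo <- b + r[1L]; hi <- min(b + r[2L] - 1L, n)
      if (lo <= n) { acc[lo] <- acc[lo] + 1; if (hi < n) acc[hi + 1L] <- acc[hi + 1L] - 1 }
    }
    X[, 1L + J + l] <- cumsum(acc[seq_len(n)])
  }
  # mask: bins with a spike in the preceding mask_ms (inclusive of spike bin)
  w <- as.integer(round(mask_ms / dt))
  acc <- numeric(n + 1L)
  for (b in sb) {
    hi <- min(b + w - 1L, n)
    acc[b] <- acc[b] + 1; if (hi < n) acc[hi + 1L] <- acc[hi + 1L] - 1
  }
  mask <- cumsum(acc[seq_len(n)]) > 0
  list(X = X, mask = mask, dt = dt, bases = bases, spike_bins = sb)
}

#' Least-squares estimation of the subthreshold parameters
#'
#' Solves the masked least-squares problem for \eqn{\theta_{sub} = (v_b, a_j,
#' b_l)} by QR factorization (numerically preferable to the normal-equations
#' formula, with which it agrees on well-conditioned problems).
#'
#' @param voltage recorded subthreshold voltage (mV).
#' @param stim a [stimulus_trace()] in pA.
#' @param spikes a [spike_train()].
#' @param bases filter bases.
#' @param cfg a [fit_config()].
#' @return List: `vb`, `k_coefs` (density, mV/pA/ms), `hv_coefs` (mV),
#'   `theta_sub` (raw regression coefficients), `rmse` (training, unmasked
#'   bins, mV), `design`.
#' @export
fit_subthreshold <- function(voltage, stim, spikes, bases = default_bases(),
                             cfg = fit_config()) {
  d <- build_design(stim, spikes, bases, cfg$postspike_mask_ms)
  keep <- !d$mask
  Xk <- d$X[keep, , drop = FALSE]
  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    bad <- setdiff(seq_len(ncol(Xk)), qrX$pivot[seq_len(qrX$rank)])
    stop("design matrix is rank deficient; degenerate columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- .lm.fit(Xk, voltage[keep])
  theta <- fit$coefficients
  J <- bases$k$n_bins; L <- bases$hv$n_bins
  list(vb = theta[1L],
       k_coefs = theta[1L + seq_len(J)] / d$dt,
       hv_coefs = theta[1L + J + seq_len(L)],
       theta_sub = theta,
       rmse = sqrt(mean(fit$residuals^2)),
       design = d)
}

# design of the threshold stage: y(t) = (vhat(t), -1, hth basis columns)
build_threshold_design <- function(vhat, spike_bins, basis_hth, dt) {
  n <- length(vhat)
  M <- basis_hth$n_bins
  Y <- matrix(0, n, 2L + M)
  Y[, 1L] <- vhat
  Y[, 2L] <- -1
  for (m in seq_len(M)) {
    r <- bin_lag_range(basis_hth, m, dt, postspike = TRUE)
    acc <- numeric(n + 1L)
    for (b in spike_bins) {
      lo <- b + r[1L]; hi <- min(b + r[2L] - 1L, n)
      if (lo <= n) { acc[lo] <- acc[lo] + 1; if (hi < n) acc[hi + 1L] <- acc[hi + 1L] - 1 }
    }
    Y[, 2L + m] <- -cumsum(acc[seq_len(n)])  # enters with a minus sign
  }
  Y
}

# second-difference penalty matrix on the threshold-filter components of
# theta_th (positions 3..2+M): alpha * sum (theta_{m+1} - theta_m)^2; applied
# to the scaled coefficients c_m / delta_v, which keeps the penalized
# log-likelihood concave in theta_th
penalty_matrix <- function(M) {
  P <- matrix(0, 2L + M, 2L + M)
  if (M >= 2) {
    D <- diff(diag(M))
    P[3:(2 + M), 3:(2 + M)] <- crossprod(D)
  }
  P
}

#' Point-process log-likelihood of the threshold stage
#'
#' \eqn{\ell(\theta_{th}) = \sum_{t_s} y(t_s)^T\theta_{th} - \Delta t \sum_t
#' \exp(y(t)^T\theta_{th}) - \alpha\,\theta^T P\,\theta}, with
#' \eqn{y(t) = (\hat v(t), -1, -\sum f_1(t-t_s), \ldots)} and
#' \eqn{\theta_{th} = \Delta v^{-1}(1, v_{th}, c_1, \ldots, c_M)}. Concave in
#' \eqn{\theta_{th}}; the analytic gradient and Hessian are returned for use
#' by Newton ascent and by correctness tests.
#'
#' @param theta parameter vector (length 2 + M).
#' @param Y threshold design matrix.
#' @param spike_bins 1-based spike bin indices.
#' @param dt grid step (ms).
#' @param alpha smoothness penalty weight.
#' @param clip exponent cap.
#' @return List `value`, `gradient`, `hessian`.
#' @export
threshold_loglik <- function(theta, Y, spike_bins, dt, alpha = 0, clip = 30) {
  P <- penalty_matrix(ncol(Y) - 2L)
  eta <- pmin(as.numeric(Y %*% theta), clip)
  lam <- exp(eta)
  value <- sum(eta[spike_bins]) - dt * sum(lam) -
    alpha * as.numeric(theta %*% P %*% theta)
  grad <- colSums(Y[spike_bins, , drop = FALSE]) - dt * as.numeric(crossprod(Y, lam)) -
    2 * alpha * as.numeric(P %*% theta)
  hess <- -dt * crossprod(Y * lam, Y) - 2 * alpha * P
  list(value = value, gradient = grad, hessian = hess)
}

#' Maximum-likelihood estimation of the threshold parameters
#'
#' Newton ascent of the penalized point-process log-likelihood with step
#' halving, keeping the stage-1 subthreshold prediction fixed. When
#' validation recordings are supplied, the penalty weight is chosen from
#' `cfg$alpha_grid` as the one with the largest unpenalized log-likelihood on
#' the validation data; otherwise the first grid value is used.
#'
#' @param sub output of [fit_subthreshold()].
#' @param spikes training [spike_train()].
#' @param bases filter bases.
#' @param cfg a [fit_config()].
#' @param validation optional list of [recording()]s for alpha selection.
#' @return List: `vth`, `delta_v`, `hth_coefs`, `theta_th`, `alpha`,
#'   `n_iter`, `converged`, `val_loglik` (per grid value, if validated).
#' @export
fit_threshold <- function(sub, spikes, bases = default_bases(),
                          cfg = fit_config(), validation = NULL) {
  d <- sub$design
  vhat <- as.numeric(d$X %*% sub$theta_sub)
  Y <- build_threshold_design(vhat, d$spike_bins, bases$hth, d$dt)
  if (length(d$spike_bins) == 0) stop("no spikes; threshold stage undefined")
  init <- c(1, mean(vhat) + 2 * stats::sd(vhat), numeric(bases$hth$n_bins)) / cfg$delta_v0
  fits <- lapply(cfg$alpha_grid, function(a)
    newton_ascent(init, Y, d$spike_bins, d$dt, a, cfg))
  if (!is.null(validation) && length(cfg$alpha_grid) > 1L) {
    val <- vapply(fits, function(f)
      validation_loglik(f$theta, sub, bases, validation), numeric(1))
    best <- which.max(val)
  } else {
    val <- NULL
    best <- 1L
  }
  f <- fits[[best]]
  theta <- f$theta
  delta_v <- 1 / theta[1L]
  list(vth = theta[2L] * delta_v,
       delta_v = delta_v,
       hth_coefs = theta[-(1:2)] * delta_v,
       theta_th = theta,
       alpha = cfg$alpha_grid[best],
       n_iter = f$n_iter, converged = f$converged,
       val_loglik = val)
}

newton_ascent <- function(theta, Y, spike_bins, dt, alpha, cfg) {
  ll <- threshold_loglik(theta, Y, spike_bins, dt, alpha)
  for (it in seq_len(cfg$max_iter)) {
    if (max(abs(ll$gradient)) < cfg$newton_tol)
      return(list(theta = theta, n_iter = it - 1L, converged = TRUE,
                  value = ll$value))
    step <- solve(-ll$hessian, ll$gradient)
    s <- 1
    repeat {
      cand <- theta + s * step
      llc <- threshold_loglik(cand, Y, spike_bins, dt, alpha)
      if (llc$value >= ll$value || s < 1e-10) break
      s <- s / 2
    }
    if (llc$value < ll$value)
      stop("Newton ascent stalled at iteration ", it,
           "; log-likelihood ", format(ll$value))
    theta <- cand; ll <- llc
  }
  if (max(abs(ll$gradient)) < cfg$newton_tol)
    return(list(theta = theta, n_iter = cfg$max_iter, converged = TRUE,
                value = ll$value))
  stop("threshold Newton did not converge in ", cfg$max_iter,
       " iterations; max|grad| = ", format(max(abs(ll$gradient))))
}

# unpenalized log-likelihood of held-out recordings under stage-1 parameters
# and a candidate theta_th
validation_loglik <- function(theta, sub, bases, validation) {
  total <- 0
  for (rec in validation) {
    d <- build_design(rec$stimulus, rec$spikes, bases)
    vhat <- as.numeric(d$X %*% sub$theta_sub)
    Y <- build_threshold_design(vhat, d$spike_bins, bases$hth, d$dt)
    ll <- threshold_loglik(theta, Y, d$spike_bins, d$dt, alpha = 0)
    total <- total + ll$value
  }
  total
}

#' Normalized log-likelihood in bits per spike
#'
#' Log-likelihood of the spikes under the model relative to a homogeneous
#' Poisson process of the same empirical rate, divided by the number of
#' spikes: \eqn{L = \frac{1}{n}\log_2 \frac{P(s|i;\theta)}
#' {P(n|\bar\lambda)}} with \eqn{\log P(n|\bar\lambda) = n\log\bar\lambda -
#' \bar\lambda T}. Positive values mean the model beats the rate-matched
#' Poisson reference.
#'
#' @param p an [srm_params()].
#' @param rec a [recording()] with at least one spike.
#' @return Bits per spike.
#' @export
normalized_loglik <- function(p, rec) {
  ns <- n_spikes(rec$spikes)
  if (ns == 0) stop("empty spike train; normalized log-likelihood undefined")
  dt <- rec$dt
  v <- subthreshold_voltage(p, rec$stimulus, rec$spikes)
  lam <- suppressWarnings(conditional_intensity(p, v, rec$spikes, dt))
  sb <- spike_bins_of(rec$spikes, dt, rec$stimulus$n)
  ll_model <- sum(log(lam[sb])) - dt * sum(lam)
  T_ms <- rec$stimulus$n * dt
  lam_bar <- ns / T_ms
  ll_pois <- ns * log(lam_bar) - lam_bar * T_ms
  (ll_model - ll_pois) / (ns * log(2))
}

#' Timescale and resistance of the membrane filter
#'
#' Fits a single exponential \eqn{A e^{-t/\tau}} to the tail of the membrane
#' filter (skipping initial bins dominated by the fast pipette transient) and
#' reports the decay constant, the amplitude, and the electrical resistance
#' given by the analytic area of the fitted exponential, \eqn{R = A\tau}.
#'
#' @param k_coefs filter density per bin (mV/pA/ms).
#' @param basis the k [basis_spec()].
#' @param skip_bins initial bins excluded from the tail fit.
#' @return List `tau_k` (ms), `amplitude` (mV/pA/ms), `resistance` (MOhm).
#' @export
filter_summary <- function(k_coefs, basis, skip_bins = 1) {
  stopifnot(length(k_coefs) == basis$n_bins)
  idx <- (skip_bins + 1):basis$n_bins
  if (length(idx) < 5) stop("need at least 5 tail bins for the exponential fit")
  t <- basis$start + (idx - 0.5) * basis$width
  y <- k_coefs[idx]
  A0 <- max(y[1], 1e-8); tau0 <- max(diff(range(t)) / 3, basis$width)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau), start = list(A = A0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("filter tail fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  A <- unname(cf["A"]); tau <- unname(cf["tau"])
  if (tau <= 0) stop("filter tail fit produced non-positive tau")
  list(tau_k = tau, amplitude = A, resistance = 1000 * A * tau)
}

#' Fit the full SRM to a training recording
#'
#' Two-stage estimation: least squares for the subthreshold parameters on the
#' post-spike-masked voltage, then penalized Newton maximum likelihood for the
#' threshold parameters with the subthreshold stage held fixed.
#'
#' @param train a [recording()] with voltage (the 99 s single-trial protocol).
#' @param bases filter bases.
#' @param cfg a [fit_config()].
#' @param validation optional list of validation [recording()]s used to
#'   select the smoothness penalty.
#' @return List: `params` (an [srm_params()]), `sub`, `th` (stage outputs).
#' @export
fit_srm <- function(train, bases = default_bases(), cfg = fit_config(),
                    validation = NULL) {
  stopifnot(inherits(train, "recording"), !is.null(train$voltage))
  sub <- fit_subthreshold(train$voltage, train$stimulus, train$spikes, bases, cfg)
  th <- fit_threshold(sub, train$spikes, bases, cfg, validation)
  params <- srm_params(sub$vb, sub$k_coefs, sub$hv_coefs, th$vth, th$hth_coefs,
                       th$delta_v, bases = bases, cell_id = train$cell_id)
  list(params = params, sub = sub, th = th)
}

#' Validate a fitted SRM on held-out trials
#'
#' Computes, over validation recordings sharing one stimulus: the RMSE of the
#' subthreshold prediction (same post-spike mask as training), the normalized
#' log-likelihood per trial, and the Md similarity between a set of simulated
#' responses and the recorded set at the standard 8 ms window.
#'
#' @param p a fitted [srm_params()].
#' @param validation list of [recording()]s (same stimulus).
#' @param cfg a [fit_config()] (for the mask length).
#' @param spec a [coincidence_spec()].
#' @param seed seed for the simulated trains.
#' @return A `fit_report` list: `rmse_mv`, `norm_loglik_bits` (per trial),
#'   `md_score`.
#' @export
validate_srm <- function(p, validation, cfg = fit_config(),
                         spec = coincidence_spec(), seed = 1) {
  stopifnot(length(validation) >= 2)
  rmse <- nll <- numeric(length(validation))
  for (i in seq_along(validation)) {
    rec <- validation[[i]]
    vhat <- subthreshold_voltage(p, rec$stimulus, rec$spikes)
    d <- build_design(rec$stimulus, rec$spikes, p$bases, cfg$postspike_mask_ms)
    keep <- !d$mask
    rmse[i] <- if (is.null(rec$voltage)) NA_real_ else
      sqrt(mean((vhat[keep] - rec$voltage[keep])^2))
    nll[i] <- normalized_loglik(p, rec)
  }
  recorded <- trial_set(lapply(validation, `[[`, "spikes"))
  simulated <- trial_set(lapply(seq_along(validation), function(i)
    simulate_srm(p, validation[[i]]$stimulus, seed = seed + i)$spikes))
  structure(list(rmse_mv = rmse, norm_loglik_bits = nll,
                 md_score = md_similarity(simulated, recorded, spec)),
            class = "fit_report")
}
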