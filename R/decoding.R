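#' AR(1) stimulus prior
#'
#' Gaussian prior of the discretized OU stimulus: \eqn{\log P(\eta) =
#' -\frac{1}{2}\eta^T\Sigma^{-1}\eta} with the tridiagonal precision of the
#' AR(1) process with coefficient \eqn{\beta = e^{-\Delta t/\tau}}.
#'
#' @param tau OU correlation time (ms).
#' @param dt grid step (ms).
#' @param n number of time bins.
#' @return A `prior_spec` list with `tau`, `dt`, `n`, `beta`.
#' @export
prior_spec <- function(tau = 3, dt = 1, n) {
  stopifnot(tau > 0, dt > 0, n >= 2)
  structure(list(tau = tau, dt = dt, n = as.integer(n), beta = exp(-dt / tau)),
            class = "prior_spec")
}

#' Tridiagonal prior precision matrix
#'
#' \eqn{\Sigma^{-1}_{ij} = \frac{1}{1-\beta^2}} at the two corners,
#' \eqn{\frac{1+\beta^2}{1-\beta^2}} on the interior diagonal, and
#' \eqn{\frac{-\beta}{1-\beta^2}} on the first off-diagonals. Its dense
#' inverse is the AR(1) covariance \eqn{\beta^{|i-j|}}.
#'
#' @param spec a [prior_spec()].
#' @param format `"banded"` for compact lower-band storage (2 x n matrix,
#'   row 1 = diagonal) or `"dense"`.
#' @return Matrix in the requested format.
#' @export
prior_precision <- function(spec, format = c("banded", "dense")) {
  format <- match.arg(format)
  beta <- spec$beta; n <- spec$n
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  d <- 1 - beta^2
  diag_v <- c(1, rep(1 + beta^2, n - 2L), 1) / d
  off_v <- rep(-beta / d, n - 1L)
  if (format == "banded") {
    ab <- matrix(0, 2L, n)
    ab[1L, ] <- diag_v
    ab[2L, seq_len(n - 1L)] <- off_v
    ab
  } else {
    A <- diag(diag_v)
    A[cbind(1:(n - 1L), 2:n)] <- off_v
    A[cbind(2:n, 1:(n - 1L))] <- off_v
    A
  }
}

#' Banded symmetric linear algebra
#'
#' Compact lower-band storage: `ab[d + 1, j] = A[j + d, j]`, `d = 0, ...,
#' bw - 1`. `band_chol` returns the lower Cholesky factor in the same
#' storage; `band_chol_solve` solves `A x = b`; `band_logdet` is
#' \eqn{\log|A|}; `band_inv_diag` is the diagonal of \eqn{A^{-1}} (via the
#' Takahashi recurrence, exact on the band); `band_to_dense` expands the
#' symmetric matrix for testing.
#'
#' @param ab,L compact banded matrices (`L` a factor from `band_chol`).
#' @param b right-hand side vector or matrix.
#' @return See each description.
#' @export
band_chol <- function(ab) band_chol_cpp(ab)

#' @rdname band_chol
#' @export
band_chol_solve <- function(L, b) {
  bmat <- if (is.matrix(b)) b else matrix(b, ncol = 1L)
  out <- band_chol_solve_cpp(L, bmat)
  if (is.matrix(b)) out else as.numeric(out)
}

#' @rdname band_chol
#' @export
band_logdet <- function(L) 2 * sum(log(L[1L, ]))

#' @rdname band_chol
#' @export
band_inv_diag <- function(L) as.numeric(band_inv_diag_cpp(L))

#' @rdname band_chol
#' @export
band_to_dense <- function(ab) {
  bw <- nrow(ab); n <- ncol(ab)
  A <- matrix(0, n, n)
  for (d in 0:(bw - 1L)) {
    j <- seq_len(n - d)
    A[cbind(j + d, j)] <- ab[d + 1L, j]
    A[cbind(j, j + d)] <- ab[d + 1L, j]
  }
  A
}

#' Encoder bank: fitted cells and their observed spike trains
#'
#' @param entries list; each entry is a list with fields `params`
#'   ([srm_params()]), `scaling` ([scaling_spec()]), and `trains` (list of
#'   [spike_train()]s observed from that cell).
#' @return An `encoder_bank` object.
#' @export
encoder_bank <- function(entries) {
  stopifnot(all(vapply(entries, function(e)
    inherits(e$params, "srm_params") && inherits(e$scaling, "scaling_spec") &&
      length(e$trains) >= 1, logical(1))))
  structure(list(entries = entries), class = "encoder_bank")
}

#' Decoder configuration
#'
#' @param tol Newton stopping tolerance on the max absolute gradient of the
#'   log-posterior.
#' @param max_iter maximum Newton iterations.
#' @param clip exponent cap in the conditional intensity.
#' @return A `decode_config` list.
#' @export
decode_config <- function(tol = 1e-6, max_iter = 100, clip = 30) {
  structure(list(tol = tol, max_iter = max_iter, clip = clip),
            class = "decode_config")
}

# per-cell precomputation for the decoder: discretized kernel, gain, and the
# spike-history/baseline part of the exponent for each trial
decoder_cell_setup <- function(entry, n, dt, clip) {
  p <- entry$params; sc <- entry$scaling
  kd <- discretize_k(p, dt)
  gain <- sc$sigma / p$delta_v
  mu_part <- sc$mu * as.numeric(causal_conv_cpp(rep(1, n), kd))
  hv <- discretize_h(p$hv_coefs, p$bases$hv, dt)
  hth <- discretize_h(p$hth_coefs, p$bases$hth, dt)
  bases_tr <- list(); sb_tr <- list()
  for (i in seq_along(entry$trains)) {
    s <- entry$trains[[i]]
    if (abs(s$duration - n * dt) > dt / 2)
      stop("spike-train duration does not match the decoding grid")
    sb <- spike_bins_of(s, dt, n)
    hist_v <- as.numeric(spike_history_cpp(sb, hv, n))
    hist_th <- as.numeric(spike_history_cpp(sb, hth, n))
    bases_tr[[i]] <- (p$vb + mu_part + hist_v - p$vth - hist_th) / p$delta_v
    sb_tr[[i]] <- sb
  }
  list(kd = kd, gain = gain, bases = bases_tr, spike_bins = sb_tr)
}

#' MAP stimulus decoding with Laplace uncertainty
#'
#' Reconstructs the normalized stimulus \eqn{\eta} as the maximizer of the
#' log-posterior: the sum of the per-cell, per-trial point-process
#' log-likelihoods plus the AR(1) log-prior. The posterior is concave in
#' \eqn{\eta}; Newton ascent uses banded Hessian solves (the likelihood
#' Hessian bandwidth is set by the membrane-filter support). At the optimum
#' the Laplace covariance \eqn{C = (-\nabla^2 \log P)^{-1}} provides the
#' per-time posterior standard deviation (banded Takahashi inverse diagonal)
#' and the log-determinant used for mutual information.
#'
#' @param bank an [encoder_bank()] (may hold zero entries: prior-only decode).
#' @param prior a [prior_spec()] defining the grid.
#' @param cfg a [decode_config()].
#' @param eta_true optional true stimulus for convenience `r2` reporting.
#' @return A `decode_result`: `eta_map`, `sd`, `logdet_post` (log-determinant
#'   of the posterior precision), `n_iter`, `r2` (if `eta_true` given),
#'   `prior`.
#' @export
map_decode <- function(bank, prior, cfg = decode_config(), eta_true = NULL) {
  stopifnot(inherits(prior, "prior_spec"))
  n <- prior$n; dt <- prior$dt
  entries <- if (inherits(bank, "encoder_bank")) bank$entries else bank
  cells <- lapply(entries, decoder_cell_setup, n = n, dt = dt, clip = cfg$clip)
  bw <- max(2L, if (length(cells)) max(vapply(cells, function(cl) length(cl$kd), integer(1))) else 2L)
  Q <- prior_precision(prior, "banded")

  eval_state <- function(eta) {
    # returns value, gradient, per-cell summed intensities
    val <- -0.5 * quad_form_band(Q, eta)
    grad <- -band_mult(Q, eta)
    wlist <- vector("list", length(cells))
    for (j in seq_along(cells)) {
      cl <- cells[[j]]
      g <- as.numeric(causal_conv_cpp(eta, cl$kd))
      resid <- numeric(n)  # spike indicator minus dt * lambda, summed
      w <- numeric(n)
      for (i in seq_along(cl$bases)) {
        ex <- pmin(cl$bases[[i]] + cl$gain * g, cfg$clip)
        lam <- exp(ex)
        sb <- cl$spike_bins[[i]]
        val <- val + sum(ex[sb]) - dt * sum(lam)
        w <- w + lam
        resid <- resid - dt * lam
        if (length(sb)) resid[sb] <- resid[sb] + 1
      }
      grad <- grad + cl$gain * as.numeric(kernel_corr_cpp(resid, cl$kd))
      wlist[[j]] <- w
    }
    list(value = val, gradient = grad, w = wlist)
  }

  neg_hessian <- function(wlist) {
    H <- matrix(0, bw, n)
    H[1L, ] <- H[1L, ] + Q[1L, ]
    H[2L, seq_len(n - 1L)] <- H[2L, seq_len(n - 1L)] + Q[2L, seq_len(n - 1L)]
    for (j in seq_along(cells)) {
      cl <- cells[[j]]
      band_glm_hessian_acc_cpp(H, wlist[[j]], cl$kd, cl$gain^2, dt)
    }
    H
  }

  eta <- numeric(n)
  st <- eval_state(eta)
  iters <- 0L
  while (max(abs(st$gradient)) >= cfg$tol && iters < cfg$max_iter) {
    H <- neg_hessian(st$w)
    L <- band_chol(H)
    step <- band_chol_solve(L, st$gradient)
    s <- 1
    repeat {
      cand <- eta + s * step
      stc <- eval_state(cand)
      if (stc$value >= st$value || s < 1e-10) break
      s <- s / 2
    }
    if (stc$value < st$value)
      stop("decoder Newton stalled at iteration ", iters + 1L)
    eta <- cand; st <- stc
    iters <- iters + 1L
  }
  if (max(abs(st$gradient)) >= cfg$tol)
    stop("decoder did not converge in ", cfg$max_iter, " iterations; ",
         "max|grad| = ", format(max(abs(st$gradient))))
  L <- band_chol(neg_hessian(st$w))
  sd <- sqrt(band_inv_diag(L))
  res <- structure(list(eta_map = eta, sd = sd, logdet_post = band_logdet(L),
                        n_iter = iters, prior = prior),
                   class = "decode_result")
  if (!is.null(eta_true)) res$r2 <- r_squared(eta_true, eta)
  res
}

# y = A x for compact lower-banded symmetric A
band_mult <- function(ab, x) {
  bw <- nrow(ab); n <- ncol(ab)
  y <- ab[1L, ] * x
  if (bw >= 2L) for (d in 1:(bw - 1L)) {
    j <- seq_len(n - d)
    y[j + d] <- y[j + d] + ab[d + 1L, j] * x[j]
    y[j] <- y[j] + ab[d + 1L, j] * x[j + d]
  }
  y
}

quad_form_band <- function(ab, x) sum(x * band_mult(ab, x))

#' Coefficient of determination of a reconstruction
#'
#' \eqn{r^2 = 1 - \mathrm{MSE}(\eta, \hat\eta)/\mathrm{Var}(\eta)} with the
#' population variance of the true stimulus; can be negative for poor
#' reconstructions.
#'
#' @param eta_true,eta_map numeric vectors of equal length.
#' @return Scalar r-squared.
#' @export
r_squared <- function(eta_true, eta_map) {
  if (length(eta_true) != length(eta_map)) stop("length mismatch")
  v <- mean((eta_true - mean(eta_true))^2)
  if (v == 0) stop("zero-variance truth; r2 undefined")
  1 - mean((eta_true - eta_map)^2) / v
}

#' Mutual information between stimulus and spike trains
#'
#' \eqn{I(\eta;\{s_j\}) = H(\eta) - H(\eta|\{s_j\})} with Gaussian entropies
#' \eqn{H = \frac{1}{2}\log\{(2\pi e)^N |\Sigma|\}}; the conditional entropy
#' is the Monte-Carlo average of the Laplace-approximate posterior entropies
#' over decodes. Reported in bits. With no observations the posterior equals
#' the prior and the information is exactly zero.
#'
#' @param decodes list of `decode_result`s from the same prior.
#' @param prior the shared [prior_spec()].
#' @return Mutual information in bits.
#' @export
mutual_information <- function(decodes, prior) {
  stopifnot(length(decodes) >= 1)
  Q <- prior_precision(prior, "banded")
  ld_prior <- band_logdet(band_chol(Q))
  ld_post <- vapply(decodes, function(d) d$logdet_post, numeric(1))
  # H(prior) - mean H(post) = 0.5 * (mean logdet(C^-1) - logdet(Sigma^-1))
  0.5 * (mean(ld_post) - ld_prior) / log(2)
}

#' Trial count equalizing the expected spike contribution
#'
#' `round(n / (lambda * T))` trials give about `n` spikes from a cell firing
#' at `rate_hz` over `T_s` seconds; floored at one trial.
#'
#' @param rate_hz firing rate (Hz), positive.
#' @param T_s stimulus duration (s).
#' @param n_target_spikes desired expected spike count.
#' @return Integer number of trials (>= 1).
#' @export
equalize_trials <- function(rate_hz, T_s, n_target_spikes) {
  if (rate_hz <= 0) stop("rate must be positive")
  max(1L, as.integer(round(n_target_spikes / (rate_hz * T_s))))
}

#' Spike-triggered posterior uncertainty profile
#'
#' Averages the posterior standard-deviation trace in windows aligned to each
#' spike (lag 0 = spike time); the decoder's knowledge of the stimulus peaks
#' (uncertainty dips) just before the spikes that informed it.
#'
#' @param result a `decode_result`.
#' @param spikes the [spike_train()] (or list of trains) the decode used.
#' @param lag_range_ms window around each spike, e.g. `c(-100, 20)`.
#' @return List `lag_ms`, `mean_sd`, `min_lag_ms`, `min_sd`.
#' @export
spike_triggered_uncertainty <- function(result, spikes, lag_range_ms = c(-100, 20)) {
  trains <- if (inherits(spikes, "spike_train")) list(spikes) else spikes
  dt <- result$prior$dt; n <- result$prior$n
  lag_bins <- seq(as.integer(round(lag_range_ms[1] / dt)),
                  as.integer(round(lag_range_ms[2] / dt)))
  acc <- numeric(length(lag_bins)); cnt <- numeric(length(lag_bins))
  for (s in trains) {
    sb <- spike_bins_of(s, dt, n)
    for (b in sb) {
      idx <- b + lag_bins
      ok <- idx >= 1L & idx <= n
      acc[ok] <- acc[ok] + result$sd[idx[ok]]
      cnt[ok] <- cnt[ok] + 1
    }
  }
  if (all(cnt == 0)) stop("no spikes; spike-triggered profile undefined")
  mean_sd <- acc / pmax(cnt, 1)
  mean_sd[cnt == 0] <- NA_real_
  k <- which.min(mean_sd)
  list(lag_ms = lag_bins * dt, mean_sd = mean_sd,
       min_lag_ms = lag_bins[k] * dt, min_sd = mean_sd[k])
}

#' Single-cell decoding experiment across a pool
#'
#' For each cell: samples `n_stimuli` fresh OU stimuli, simulates the cell's
#' response (`n_trials` per stimulus), MAP-decodes each stimulus from those
#' spike trains alone, and records the mean r-squared and mutual information.
#' Firing rate explains most of the raw performance, so the pool-wide linear
#' relationships of r-squared and information on rate are removed and the
#' residuals reported, isolating the age effect at matched rate.
#'
#' @param pool a [cell_pool()].
#' @param duration_ms stimulus duration per decode.
#' @param n_stimuli decodes per cell.
#' @param n_trials trials per stimulus (single spike trains by default).
#' @param tau OU/prior correlation time (ms).
#' @param dt decoding grid step (ms).
#' @param seed RNG seed.
#' @param cfg a [decode_config()].
#' @return A data.frame: cell_id, age, rate_hz, mean_r2, info_bits,
#'   resid_r2, resid_info.
#' @export
decode_experiment <- function(pool, duration_ms = 2000, n_stimuli = 10,
                              n_trials = 1, tau = 3, dt = 1, seed = 1,
                              cfg = decode_config()) {
  stopifnot(inherits(pool, "cell_pool"))
  n <- as.integer(round(duration_ms / dt))
  prior <- prior_spec(tau, dt, n)
  rows <- lapply(seq_along(pool$cells), function(ci) {
    cell <- pool$cells[[ci]]
    r2s <- numeric(n_stimuli); decs <- vector("list", n_stimuli)
    nsp <- 0
    for (k in seq_len(n_stimuli)) {
      eta <- sample_ou(ou_spec(tau, dt, duration_ms, seed = seed + 7919L * ci + k))
      cur <- scale_stimulus(eta, cell$scaling)
      trains <- lapply(seq_len(n_trials), function(tr)
        simulate_srm(cell$params, cur, seed = seed + 104729L * ci + 97L * k + tr)$spikes)
      nsp <- nsp + sum(vapply(trains, n_spikes, numeric(1)))
      bank <- encoder_bank(list(list(params = cell$params,
                                     scaling = cell$scaling, trains = trains)))
      dec <- map_decode(bank, prior, cfg, eta_true = eta$values)
      r2s[k] <- dec$r2; decs[[k]] <- dec
    }
    data.frame(cell_id = cell$cell_id, age = cell$age,
               rate_hz = 1000 * nsp / (n_trials * n_stimuli * duration_ms),
               mean_r2 = mean(r2s),
               info_bits = mutual_information(decs, prior))
  })
  df <- do.call(rbind, rows)
  df$resid_r2 <- stats::resid(stats::lm(mean_r2 ~ rate_hz, data = df))
  df$resid_info <- stats::resid(stats::lm(info_bits ~ rate_hz, data = df))
  df
}
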