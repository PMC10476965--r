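test_that("prior precision has the stated tridiagonal entries and AR(1) inverse", {
  ps <- prior_spec(tau = 3, dt = 0.1, n = 50)
  beta <- exp(-0.1 / 3)
  ab <- prior_precision(ps, "banded")
  expect_equal(ab[1, 1], 1 / (1 - beta^2))
  expect_equal(ab[1, 50], 1 / (1 - beta^2))
  expect_equal(ab[1, 25], (1 + beta^2) / (1 - beta^2))
  expect_equal(ab[2, 10], -beta / (1 - beta^2))
  dense <- prior_precision(ps, "dense")
  cov_ar1 <- beta^abs(outer(0:49, 0:49, "-"))
  expect_lt(max(abs(solve(dense) - cov_ar1)), 1e-10)
  # PSD quadratic form
  set.seed(3)
  for (k in 1:10) {
    x <- rnorm(50)
    expect_gte(as.numeric(x %*% dense %*% x), 0)
  }
  # tau << dt: beta ~ 0, the prior approaches independence (identity)
  ps0 <- prior_spec(tau = 0.1, dt = 1, n = 10)
  expect_lt(max(abs(prior_precision(ps0, "dense") - diag(10))), 1e-4)
})

test_that("banded Cholesky machinery agrees with dense linear algebra", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 40; bw <- sample(2:6, 1)
    A <- crossprod(matrix(rnorm(n * n), n)) + diag(n) * (n / 2)
    A[abs(outer(1:n, 1:n, "-")) >= bw] <- 0
    ab <- matrix(0, bw, n)
    for (d in 0:(bw - 1)) ab[d + 1, 1:(n - d)] <- A[cbind((1 + d):n, 1:(n - d))]
    L <- band_chol(ab)
    b <- rnorm(n)
    expect_equal(band_chol_solve(L, b), solve(A, b), tolerance = 1e-9)
    expect_equal(band_logdet(L), as.numeric(determinant(A)$modulus),
                 tolerance = 1e-9)
    expect_equal(band_inv_diag(L), diag(solve(A)), tolerance = 1e-9)
    expect_equal(band_to_dense(ab), A)
  }
  # non-PD input is rejected
  bad <- matrix(c(1, 2, 1, 0), 2, 2)  # off-diagonal dominates
  expect_error(band_chol(bad), "positive definite")
})

test_that("an empty encoder bank returns the prior as posterior", {
  prior <- prior_spec(3, 1, 500)
  dec <- map_decode(encoder_bank(list()), prior)
  expect_equal(dec$eta_map, rep(0, 500))
  expect_equal(max(abs(dec$sd - 1)), 0, tolerance = 0.01)  # stationary sd 1
  expect_equal(mutual_information(list(dec), prior), 0, tolerance = 1e-9)
})

test_that("banded MAP decode matches a dense Newton oracle", {
  cell <- make_test_cell()
  n <- 200; dt <- 1
  eta <- sample_ou(ou_spec(3, dt, n * dt, seed = 21))
  cur <- scale_stimulus(eta, cell$scaling)
  trains <- lapply(1:3, function(i) simulate_srm(cell$params, cur, seed = 500 + i)$spikes)
  prior <- prior_spec(3, dt, n)
  dec <- map_decode(encoder_bank(list(list(params = cell$params,
                                           scaling = cell$scaling,
                                           trains = trains))), prior)
  # dense oracle: independent reconstruction of the posterior with plain
  # matrix algebra (dense convolution matrix, dense solves)
  p <- cell$params
  kd <- discretize_k(p, dt)
  Kmat <- matrix(0, n, n)
  for (t in 1:n) for (u in 0:min(t - 1, length(kd) - 1))
    Kmat[t, t - u] <- kd[u + 1]
  gain <- cell$scaling$sigma / p$delta_v
  hv <- discretize_h(p$hv_coefs, p$bases$hv, dt)
  hth <- discretize_h(p$hth_coefs, p$bases$hth, dt)
  mu_part <- as.numeric(Kmat %*% rep(cell$scaling$mu, n))
  bases_tr <- lapply(trains, function(s) {
    sb <- round(s$times / dt) + 1
    hist_v <- hist_th <- numeric(n)
    for (b in sb) {
      lags <- seq_len(n - b)
      hist_v[b + lags] <- hist_v[b + lags] + c(hv, numeric(n))[lags]
      hist_th[b + lags] <- hist_th[b + lags] + c(hth, numeric(n))[lags]
    }
    (p$vb + mu_part + hist_v - p$vth - hist_th) / p$delta_v
  })
  Q <- prior_precision(prior, "dense")
  spike_ind <- lapply(trains, function(s) {
    v <- numeric(n); v[round(s$times / dt) + 1] <- 1; v
  })
  grad_f <- function(x) {
    g <- -as.numeric(Q %*% x)
    for (i in seq_along(trains)) {
      lam <- exp(bases_tr[[i]] + gain * as.numeric(Kmat %*% x))
      g <- g + gain * as.numeric(crossprod(Kmat, spike_ind[[i]] - dt * lam))
    }
    g
  }
  hess_f <- function(x) {
    H <- Q
    for (i in seq_along(trains)) {
      lam <- exp(bases_tr[[i]] + gain * as.numeric(Kmat %*% x))
      H <- H + gain^2 * dt * crossprod(Kmat * lam, Kmat)
    }
    H
  }
  x <- numeric(n)
  for (it in 1:50) {
    g <- grad_f(x)
    if (max(abs(g)) < 1e-10) break
    x <- x + solve(hess_f(x), g)
  }
  expect_lt(max(abs(dec$eta_map - x)), 1e-6)
  Hd <- hess_f(x)
  expect_lt(max(abs(dec$sd - sqrt(diag(solve(Hd))))), 1e-6)
  expect_equal(dec$logdet_post, as.numeric(determinant(Hd)$modulus),
               tolerance = 1e-8)
})

test_that("r-squared follows its definition on hand-sized examples", {
  eta <- c(1, 2, 3, 4)
  expect_equal(r_squared(eta, eta), 1)
  expect_equal(r_squared(eta, rep(mean(eta), 4)), 0)
  guess <- c(1, 2, 2, 5)
  expect_equal(r_squared(eta, guess), 1 - mean(c(0, 0, 1, 1)) / 1.25)
  expect_error(r_squared(rep(2, 4), eta), "variance")
  expect_lt(r_squared(eta, -eta), 0)  # worse than the mean
})

test_that("information is non-negative and increases with trial count", {
  cell <- make_test_pool(1, target_hz = 5, seed = 3)$cells[[3]]
  n <- 1500; dt <- 1
  prior <- prior_spec(3, dt, n)
  info_at <- function(n_trials, seed) {
    eta <- sample_ou(ou_spec(3, dt, n * dt, seed = seed))
    cur <- scale_stimulus(eta, cell$scaling)
    trains <- lapply(seq_len(n_trials), function(i)
      simulate_srm(cell$params, cur, seed = seed + 10 * i)$spikes)
    dec <- map_decode(encoder_bank(list(list(params = cell$params,
                                             scaling = cell$scaling,
                                             trains = trains))), prior,
                      eta_true = eta$values)
    c(info = mutual_information(list(dec), prior), r2 = dec$r2)
  }
  res1 <- sapply(1:6, function(k) info_at(1, 900 + k))
  res9 <- sapply(1:6, function(k) info_at(9, 900 + k))
  expect_true(all(res1["info", ] >= 0))
  expect_gt(mean(res9["info", ]), mean(res1["info", ]))
  expect_gt(mean(res9["r2", ]), mean(res1["r2", ]))
})

test_that("trial equalization reproduces the protocol arithmetic", {
  expect_identical(equalize_trials(2, 10, 140), 7L)
  expect_identical(equalize_trials(2, 10, 20), 1L)
  expect_identical(equalize_trials(500, 10, 140), 1L)  # floor at one trial
  expect_error(equalize_trials(0, 10, 140), "positive")
})

test_that("posterior z-scores are calibrated within the Laplace sanity band", {
  cell <- make_test_pool(1, target_hz = 5, seed = 4)$cells[[3]]
  zs <- unlist(lapply(1:4, function(k) {
    n <- 1500; dt <- 1
    eta <- sample_ou(ou_spec(3, dt, n * dt, seed = 700 + k))
    cur <- scale_stimulus(eta, cell$scaling)
    trains <- lapply(1:3, function(i)
      simulate_srm(cell$params, cur, seed = 750 + 10 * k + i)$spikes)
    dec <- map_decode(encoder_bank(list(list(params = cell$params,
                                             scaling = cell$scaling,
                                             trains = trains))),
                      prior_spec(3, dt, n))
    (eta$values - dec$eta_map) / dec$sd
  }))
  expect_gt(var(zs), 0.7)
  expect_lt(var(zs), 1.3)
})

test_that("spike-triggered uncertainty dips before the spike", {
  # hand-built result: uniform sd gives a flat profile
  fake <- structure(list(sd = rep(0.5, 1000), prior = prior_spec(3, 1, 1000)),
                    class = "decode_result")
  s <- spike_train(c(200, 500, 800), 1000)
  prof <- spike_triggered_uncertainty(fake, s, c(-50, 10))
  expect_true(all(prof$mean_sd == 0.5))
  # hand-built average over two spikes
  sd_tr <- seq(0, 0.999, by = 0.001)
  fake2 <- structure(list(sd = sd_tr, prior = prior_spec(3, 1, 1000)),
                     class = "decode_result")
  s2 <- spike_train(c(300, 600), 1000)
  prof2 <- spike_triggered_uncertainty(fake2, s2, c(-2, 2))
  expect_equal(prof2$mean_sd, (sd_tr[301 + (-2:2)] + sd_tr[601 + (-2:2)]) / 2)
  expect_error(spike_triggered_uncertainty(fake, spike_train(numeric(0), 1000)),
               "no spikes")
  # real decode: informative cell, uncertainty minimum at/just before lag 0
  cell <- make_test_pool(1, target_hz = 6, seed = 5)$cells[[3]]
  n <- 1500
  eta <- sample_ou(ou_spec(3, 1, n, seed = 61))
  cur <- scale_stimulus(eta, cell$scaling)
  trains <- lapply(1:5, function(i) simulate_srm(cell$params, cur, seed = 62 + i)$spikes)
  dec <- map_decode(encoder_bank(list(list(params = cell$params,
                                           scaling = cell$scaling,
                                           trains = trains))),
                    prior_spec(3, 1, n))
  prof3 <- spike_triggered_uncertainty(dec, trains, c(-100, 50))
  expect_lte(prof3$min_lag_ms, 0)
  expect_lt(prof3$min_sd, mean(dec$sd))
})

test_that("decode experiment reports rate-residualized performance", {
  pool <- make_test_pool(1, target_hz = 4, seed = 6)
  df <- decode_experiment(pool, duration_ms = 1200, n_stimuli = 3, seed = 9)
  expect_identical(nrow(df), 3L)
  expect_true(all(is.finite(df$mean_r2)))
  expect_true(all(df$info_bits >= 0))
  # residual definition: subtracting the pool-wide line fit
  fit <- lm(mean_r2 ~ rate_hz, data = df)
  expect_equal(df$resid_r2, unname(resid(fit)), tolerance = 1e-12)
  expect_equal(sum(df$resid_r2), 0, tolerance = 1e-10)
})
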