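# moderate-scale ground-truth recording shared by the recovery tests
fit_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cell <- make_test_cell(tau_k = 20, r_mohm = 250, hv1 = -2, hth1 = 5,
                             vth = -51, delta_v = 1)
      # fine grid: the threshold stage maximizes the point-process likelihood,
      # whose agreement with the Bernoulli generator improves as dt shrinks
      eta <- sample_ou(ou_spec(3, 0.2, 40000, seed = 101))
      cur <- scale_stimulus(eta, cell$scaling)
      rec <- simulate_srm(cell$params, cur, seed = 102)
      cache <<- list(cell = cell, rec = rec)
    }
    cache
  }
})

test_that("design matrix equals a per-bin double-loop construction", {
  b <- small_bases()
  stim <- scale_stimulus(sample_ou(ou_spec(3, 1, 1000, seed = 7)),
                         scaling_spec(30, 15))
  s <- spike_train(c(100, 340, 720), 1000)
  d <- build_design(stim, s, b)
  n <- 1000; i <- stim$values
  J <- b$k$n_bins; L <- b$hv$n_bins
  oracle <- matrix(0, n, 1 + J + L); oracle[, 1] <- 1
  for (t in seq_len(n)) {
    for (u in 0:min(t - 1, b$k$support - 1)) {
      j <- basis_bin(b$k, u)
      if (!is.na(j)) oracle[t, 1 + j] <- oracle[t, 1 + j] + i[t - u]
    }
    for (ts in c(100, 340, 720)) {
      lag <- (t - 1) - ts
      if (lag >= 1) {
        l <- basis_bin(b$hv, lag)
        if (!is.na(l)) oracle[t, 1 + J + l] <- oracle[t, 1 + J + l] + 1
      }
    }
  }
  expect_equal(d$X, oracle, tolerance = 1e-10)
  # mask covers 25 ms from each spike, inclusive of the spike bin
  expect_true(all(d$mask[101:125]))
  expect_false(d$mask[126])
  expect_false(any(d$mask[1:100]))
})

test_that("degenerate designs are rejected with named columns", {
  b <- small_bases()
  z <- stimulus_trace(rep(0, 2000), 1, "pA")  # no stimulus variance
  s <- spike_train(numeric(0), 2000)
  expect_error(fit_subthreshold(rep(-70, 2000), z, s, b), "rank deficient")
})

test_that("subthreshold least squares recovers noiseless generative parameters", {
  fx <- fit_fixture()
  rec <- fx$rec; truth <- fx$cell$params
  sub <- fit_subthreshold(rec$voltage, rec$stimulus, rec$spikes,
                          bases = truth$bases)
  expect_equal(sub$vb, truth$vb, tolerance = 1e-10)
  expect_equal(sub$k_coefs, truth$k_coefs, tolerance = 1e-10)
  expect_equal(sub$hv_coefs, truth$hv_coefs, tolerance = 1e-10)
  expect_lt(sub$rmse, 1e-9)
})

test_that("constant voltage with no input fits as pure bias", {
  b <- small_bases()
  set.seed(11)
  stim <- stimulus_trace(rnorm(3000, 0, 10), 1, "pA")  # variance, zero effect
  s <- spike_train(c(500, 1500), 3000)
  v <- rep(-63.5, 3000)
  sub <- fit_subthreshold(v, stim, s, b)
  expect_equal(sub$vb, -63.5, tolerance = 1e-10)
  expect_equal(sub$k_coefs, rep(0, 6), tolerance = 1e-10)
  expect_equal(sub$hv_coefs, rep(0, 2), tolerance = 1e-10)
})

test_that("masked bins never influence the subthreshold solution", {
  fx <- fit_fixture()
  rec <- fx$rec
  sub <- fit_subthreshold(rec$voltage, rec$stimulus, rec$spikes,
                          bases = fx$cell$params$bases)
  d <- sub$design
  v2 <- rec$voltage
  v2[d$mask] <- 1e6  # sentinel garbage in masked bins
  sub2 <- fit_subthreshold(v2, rec$stimulus, rec$spikes,
                           bases = fx$cell$params$bases)
  expect_identical(sub2$theta_sub, sub$theta_sub)
})

test_that("QR solution agrees with the normal-equations formula on a toy", {
  b <- small_bases()
  stim <- scale_stimulus(sample_ou(ou_spec(3, 1, 4000, seed = 13)),
                         scaling_spec(40, 20))
  s <- spike_train(c(700, 1900, 3100), 4000)
  set.seed(14)
  v <- -70 + 0.02 * stim$values + rnorm(4000, 0, 0.5)
  d <- build_design(stim, s, b)
  X <- d$X[!d$mask, ]; y <- v[!d$mask]
  sub <- fit_subthreshold(v, stim, s, b)
  normal_eq <- solve(crossprod(X), crossprod(X, y))
  expect_equal(sub$theta_sub, as.numeric(normal_eq), tolerance = 1e-8)
})

test_that("threshold log-likelihood gradient and Hessian are exact and concave", {
  fx <- fit_fixture()
  rec <- fx$rec
  sub <- fit_subthreshold(rec$voltage, rec$stimulus, rec$spikes,
                          bases = fx$cell$params$bases)
  d <- sub$design
  # restrict to 1 s for the finite-difference oracle
  n1 <- 2000
  vhat <- as.numeric(d$X[1:n1, ] %*% sub$theta_sub)
  sb <- d$spike_bins[d$spike_bins <= n1]
  Y <- srmdecode:::build_threshold_design(vhat, sb, fx$cell$params$bases$hth, d$dt)
  set.seed(15)
  for (alpha in c(0, 5)) {
    theta <- c(1, -50, rnorm(3, 0, 0.5))
    ll <- threshold_loglik(theta, Y, sb, d$dt, alpha)
    fd <- sapply(seq_along(theta), function(j) {
      h <- 1e-6 * max(1, abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (threshold_loglik(tp, Y, sb, d$dt, alpha)$value -
       threshold_loglik(tm, Y, sb, d$dt, alpha)$value) / (2 * h)
    })
    expect_equal(ll$gradient, fd, tolerance = 1e-5)
    expect_lte(max(eigen(ll$hessian, symmetric = TRUE)$values), 1e-8)
  }
  # no spikes: the sum term vanishes
  ll0 <- threshold_loglik(c(1, -50, 0, 0, 0), Y, integer(0), d$dt, 0)
  expect_equal(ll0$value, -d$dt * sum(exp(pmin(Y %*% c(1, -50, 0, 0, 0), 30))))
})

test_that("threshold stage recovers generative parameters and is init-robust", {
  fx <- fit_fixture()
  rec <- fx$rec; truth <- fx$cell$params
  sub <- fit_subthreshold(rec$voltage, rec$stimulus, rec$spikes,
                          bases = truth$bases)
  th <- fit_threshold(sub, rec$spikes, truth$bases, fit_config(alpha_grid = 0))
  expect_true(th$converged)
  expect_equal(th$delta_v, truth$delta_v, tolerance = 0.1)
  expect_equal(th$vth, truth$vth, tolerance = 0.02 * abs(truth$vth))
  # different initialization converges to the same optimum (concavity)
  th2 <- fit_threshold(sub, rec$spikes, truth$bases,
                       fit_config(alpha_grid = 0, delta_v0 = 4))
  expect_equal(th2$theta_th, th$theta_th, tolerance = 1e-5)
})

test_that("a huge smoothness penalty flattens the threshold filter", {
  fx <- fit_fixture()
  rec <- fx$rec; truth <- fx$cell$params
  sub <- fit_subthreshold(rec$voltage, rec$stimulus, rec$spikes,
                          bases = truth$bases)
  th <- fit_threshold(sub, rec$spikes, truth$bases,
                      fit_config(alpha_grid = 1e8))
  expect_lt(max(th$hth_coefs) - min(th$hth_coefs),
            0.01 * max(abs(th$hth_coefs)))
})

test_that("normalized log-likelihood is zero for a rate-matched flat model", {
  b <- small_bases()
  z <- stimulus_trace(rep(0, 20000), 1, "pA")
  set.seed(16)
  times <- sort(sample(seq(0, 19999), 60))
  s <- spike_train(times, 20000)
  lam_bar <- 60 / 20000
  flat <- srm_params(-70 + log(lam_bar), rep(0, 6), rep(0, 2), -70,
                     rep(0, 3), 1, b)
  rec <- recording(z, NULL, s)
  expect_equal(normalized_loglik(flat, rec), 0, tolerance = 1e-12)
  expect_error(normalized_loglik(flat, recording(z, NULL, spike_train(numeric(0), 20000))),
               "empty")
})

test_that("normalized log-likelihood matches a hand-computed 3-spike example", {
  b <- small_bases()
  # k = 0, no history: lambda depends only on vb - vth
  p <- srm_params(-68, rep(0, 6), rep(0, 2), -70, rep(0, 3), 2, b)
  z <- stimulus_trace(rep(0, 1000), 1, "pA")
  s <- spike_train(c(100, 450, 800), 1000)
  rec <- recording(z, NULL, s)
  lam <- exp(1)  # (vb - vth)/dv = 1, in 1/ms
  ll_model <- 3 * 1 - 1 * 1000 * lam
  lam_bar <- 3 / 1000
  ll_pois <- 3 * log(lam_bar) - lam_bar * 1000
  expect_equal(normalized_loglik(p, rec), (ll_model - ll_pois) / (3 * log(2)))
})

test_that("better-than-Poisson encoders score positive bits per spike", {
  fx <- fit_fixture()
  expect_gt(normalized_loglik(fx$cell$params, fx$rec), 0)
})

test_that("filter summary extracts tail timescale and resistance", {
  basis <- basis_spec(44, 8, 0)
  centers <- (seq_len(44) - 0.5) * 8
  # pure exponential: closed-form area R = A * tau
  A <- 0.012; tau <- 40
  kc <- A * exp(-centers / tau)
  fs <- filter_summary(kc, basis, skip_bins = 0)
  expect_equal(fs$tau_k, 40, tolerance = 1e-6)
  expect_equal(fs$resistance, 1000 * A * tau, tolerance = 1e-6)
  # fast pipette transient + slow tail: the tail fit sees only the slow part
  kc2 <- 0.08 * exp(-centers / 1) + kc
  fs2 <- filter_summary(kc2, basis, skip_bins = 1)
  expect_equal(fs2$tau_k, 40, tolerance = 0.02)
  # noisy coefficients still recover the timescale within 10%
  set.seed(17)
  fs3 <- filter_summary(kc * (1 + rnorm(44, 0, 0.05)), basis, skip_bins = 0)
  expect_equal(fs3$tau_k, 40, tolerance = 0.1 * 40)
})

test_that("full two-stage fit validates well on held-out trials", {
  fx <- fit_fixture()
  cell <- fx$cell
  val_eta <- sample_ou(ou_spec(3, 0.5, 10000, seed = 103))
  val_cur <- scale_stimulus(val_eta, cell$scaling)
  validation <- lapply(1:9, function(tr)
    simulate_srm(cell$params, val_cur, seed = 200 + tr))
  fit <- fit_srm(fx$rec, bases = cell$params$bases,
                 cfg = fit_config(alpha_grid = c(0, 10)),
                 validation = validation)
  rep <- validate_srm(fit$params, validation, seed = 33)
  expect_lt(mean(rep$rmse_mv), 0.05)     # noiseless subthreshold trials
  expect_gt(mean(rep$norm_loglik_bits), 0)
  expect_gt(rep$md_score, 0.7)
  # self-similarity of the model simulations is ~1 by construction
  sim_set <- trial_set(lapply(1:6, function(tr)
    simulate_srm(fit$params, val_cur, seed = 400 + tr)$spikes))
  expect_gt(md_similarity(sim_set, sim_set), 0.99)
})
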