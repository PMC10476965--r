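test_that("coincidence counting matches the brute-force oracle", {
  spec <- coincidence_spec(8)
  set.seed(1)
  for (k in 1:20) {
    a <- poisson_train(8, 5000, 100 + k)
    b <- poisson_train(8, 5000, 200 + k)
    expect_identical(count_coincidences(a, b, spec),
                     as.integer(brute_coincidences(a, b, 8)))
    expect_identical(count_coincidences(a, b, spec),
                     count_coincidences(b, a, spec))
  }
})

test_that("self-coincidences count total spikes for well-separated trains", {
  s <- spike_train(seq(10, 990, by = 20), 1000)
  expect_identical(count_coincidences(s, s), n_spikes(s))
  empty <- spike_train(numeric(0), 1000)
  expect_identical(count_coincidences(empty, s), 0L)
  expect_identical(count_coincidences(s, empty), 0L)
})

test_that("spikes at exactly half the window are coincident (closed boundary)", {
  a <- spike_train(100, 1000)
  b <- spike_train(104, 1000)  # exactly Delta/2 at Delta = 8
  expect_identical(count_coincidences(a, b, coincidence_spec(8)), 1L)
  b2 <- spike_train(104.001, 1000)
  expect_identical(count_coincidences(a, b2, coincidence_spec(8)), 0L)
})

test_that("coincidence ratio: identical sets give 1, disjoint give 0, Poisson matches oracle", {
  spec <- coincidence_spec(8)
  s <- spike_train(seq(50, 950, by = 50), 1000)
  A <- trial_set(list(s))
  expect_equal(coincidence_ratio(A, A, spec), 1)
  B <- trial_set(list(spike_train(seq(70, 970, by = 50), 1000)))
  expect_equal(coincidence_ratio(A, B, spec), 0)
  # definition checked by direct brute-force evaluation on 3-trial Poisson sets
  A3 <- trial_set(lapply(1:3, function(i) poisson_train(10, 2000, 300 + i)))
  B3 <- trial_set(lapply(1:3, function(i) poisson_train(10, 2000, 400 + i)))
  num <- 0
  for (a in A3$trains) for (b in B3$trains) num <- num + brute_coincidences(a, b, 8)
  expected <- (num / 9) / ((mean_spike_count(A3) + mean_spike_count(B3)) / 2)
  expect_equal(coincidence_ratio(A3, B3, spec), expected)
  expect_equal(coincidence_ratio(A3, B3, spec), coincidence_ratio(B3, A3, spec))
  empty <- trial_set(list(spike_train(numeric(0), 1000)))
  expect_error(coincidence_ratio(empty, empty), "undefined")
})

test_that("reliability is 1 for identical trials and near chance for Poisson", {
  s <- spike_train(seq(50, 1950, by = 100), 2000)
  A <- trial_set(list(s, s, s))
  expect_equal(reliability(A), 1)
  expect_error(reliability(trial_set(list(s))), "two trials")
  # chance level lambda * Delta for independent Poisson at 5 Hz, Delta = 8 ms
  rels <- sapply(1:60, function(k) {
    A <- trial_set(lapply(1:5, function(i) poisson_train(5, 20000, 1000 * k + i)))
    reliability(A)
  })
  chance <- 5 / 1000 * 8
  expect_lt(abs(mean(rels) - chance), 3 * sd(rels) / sqrt(60))
})

test_that("Md similarity is 1 for a reliable set with itself and matches the oracle", {
  spec <- coincidence_spec(8)
  # perfectly reliable set: numerator and denominator coincide exactly
  s <- spike_train(seq(25, 1975, by = 50), 2000)
  A <- trial_set(list(s, s, s))
  expect_equal(md_similarity(A, A, spec), 1)
  # jittered partner sets: compare against direct brute-force evaluation
  set.seed(5)
  jitter_set <- function(shift) trial_set(lapply(1:3, function(i)
    spike_train(sort(pmin(1999.9, pmax(0, s$times + shift + rnorm(n_spikes(s), 0, 2)))), 2000)))
  A2 <- jitter_set(0); B2 <- jitter_set(0)
  num <- 0
  for (a in A2$trains) for (b in B2$trains) num <- num + brute_coincidences(a, b, 8)
  expected <- (num / 9) /
    ((mean_spike_count(A2) * reliability(A2, spec) +
      mean_spike_count(B2) * reliability(B2, spec)) / 2)
  expect_equal(md_similarity(A2, B2, spec), expected)
  expect_gt(md_similarity(A2, B2, spec), 0.8)
  # partner shifted far beyond the window: similarity collapses to 0
  Bfar <- jitter_set(25)
  expect_lt(md_similarity(A2, Bfar, spec), 0.1)
})

test_that("PSTH conserves spike count and matches a histogram oracle", {
  A <- trial_set(lapply(1:4, function(i) poisson_train(10, 3000, 700 + i)))
  for (w in c(20, 40)) {
    ps <- psth(A, window_ms = w, dt = 1)
    expect_equal(sum(ps$rate_hz) * 1e-3 * 1,
                 mean_spike_count(A), tolerance = 1e-9)
  }
  # single spike: rectangular bump of height 1/(W*M) per ms
  A1 <- trial_set(list(spike_train(500, 1000), spike_train(numeric(0), 1000)))
  ps <- psth(A1, window_ms = 40, dt = 1)
  expect_equal(max(ps$rate_hz), 1000 / (40 * 2))
  expect_equal(sum(ps$rate_hz > 0), 40)
  # interior bins match plain histogram-then-boxcar
  ps2 <- psth(A, window_ms = 21, dt = 1)
  counts <- rowMeans(sapply(A$trains, function(s)
    tabulate(floor(s$times) + 1L, nbins = 3000)))
  manual <- stats::filter(counts, rep(1 / 21, 21), sides = 2) * 1000
  inner <- 50:2950
  expect_equal(ps2$rate_hz[inner], as.numeric(manual[inner]), tolerance = 1e-9)
})

test_that("stimulus-PSTH cross-correlation finds shifts with the right sign", {
  set.seed(9)
  x <- as.numeric(arima.sim(list(ar = 0.95), 2000))
  out <- stim_psth_xcorr(x, x, dt = 1)
  expect_equal(out$peak_lag_ms, 0)
  expect_equal(out$peak_value, 1)
  y <- c(rep(0, 10), x[1:1990])  # response delayed by 10 ms
  out2 <- stim_psth_xcorr(x, y, dt = 1)
  expect_equal(out2$peak_lag_ms, 10)
  expect_gt(out2$peak_value, 0.99)
  expect_error(stim_psth_xcorr(x, rep(1, 2000)), "variance")
})

test_that("shuffling preserves counts, is seed-reproducible, and sits at chance", {
  A <- trial_set(lapply(1:5, function(i) poisson_train(6, 10000, 800 + i)))
  S1 <- shuffle_times(A, seed = 5)
  S2 <- shuffle_times(A, seed = 5)
  expect_identical(vapply(S1$trains, n_spikes, integer(1)),
                   vapply(A$trains, n_spikes, integer(1)))
  expect_identical(S1$trains, S2$trains)
  rels <- sapply(1:40, function(k) reliability(shuffle_times(A, seed = k)))
  chance <- mean_spike_count(A) / 10000 * 8
  expect_lt(abs(mean(rels) - chance), 4 * sd(rels) / sqrt(40) + 0.2 * chance)
})

test_that("passive-property fit recovers a known RC response", {
  dt <- 0.1; t <- seq(0, 400, by = dt)
  R <- 200; tau <- 30; I <- -10  # MOhm, ms, pA
  dv <- R * I / 1000             # mV deflection
  v <- -70 + ifelse(t >= 100, dv * (1 - exp(-(t - 100) / tau)), 0)
  fit <- fit_passive(v, dt, step_onset_ms = 100, step_pa = I, fit_window_ms = 250)
  expect_equal(fit$r_in, 200, tolerance = 0.01)
  expect_equal(fit$tau_m, 30, tolerance = 0.01)
  expect_error(fit_passive(v, dt, 100, 0), "nonzero")
  set.seed(2)
  vn <- v + rnorm(length(v), 0, 0.1)
  fitn <- fit_passive(vn, dt, 100, I, 250)
  expect_equal(fitn$r_in, 200, tolerance = 0.05)
  expect_equal(fitn$tau_m, 30, tolerance = 0.05)
})

test_that("spike detection finds crossings once per refractory window", {
  dt <- 0.1
  v <- rep(-70, 5000)
  expect_identical(n_spikes(detect_spikes(v, dt)), 0L)
  # two spikes at 100 and 300 ms, 1 ms above-threshold bumps
  for (t0 in c(100, 300)) v[(t0 / dt):(t0 / dt + 10) + 1] <- 20
  st <- detect_spikes(v, dt)
  expect_equal(st$times, c(100, 300))
  # double crossing within the refractory window collapses to one spike
  v2 <- rep(-70, 1000); v2[101:105] <- 20; v2[110:115] <- 20
  expect_identical(n_spikes(detect_spikes(v2, dt, refractory_ms = 2)), 1L)
})
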