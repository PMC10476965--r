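# Small fixtures shared across test files. Filters use shortened bases so
# decoding problems stay small; the physiology (resistances, thresholds,
# post-spike effects) matches the synthetic cohorts.

small_bases <- function() {
  list(k = basis_spec(6, 8, 0),
       hv = basis_spec(2, 25, 25),
       hth = basis_spec(3, 25, 0))
}

# one cell with the given maturity-like parameters on the small bases
make_test_cell <- function(id = "c1", tau_k = 20, r_mohm = 250, hv1 = -2,
                           hth1 = 5, vth = -50, vb = -70, delta_v = 1,
                           mu = NULL, sigma = NULL) {
  b <- small_bases()
  centers <- (seq_len(b$k$n_bins) - 0.5) * b$k$width
  shape <- exp(-centers / tau_k)
  kc <- shape * (r_mohm / 1000) / (sum(shape) * b$k$width)
  hv <- hv1 * c(1, exp(-25 / 100))
  hth <- hth1 * exp(-c(0, 25, 50) / 50)
  p <- srm_params(vb, kc, hv, vth, hth, delta_v, bases = b, cell_id = id)
  if (is.null(mu)) mu <- 1.15 * (vth - vb) / (r_mohm / 1000)
  if (is.null(sigma)) sigma <- 0.5 * mu
  list(cell_id = id, age = "mature", params = p,
       scaling = scaling_spec(mu, sigma))
}

# pool of calibrated cells spanning the three ages; rates near target_hz
make_test_pool <- function(n_per_age = 1, target_hz = 4, seed = 42) {
  ages <- c("4w", "5w", "mature")
  tau_k <- c(45, 30, 18); r <- c(450, 350, 250)
  hv1 <- c(-0.5, -1.5, -3); hth1 <- c(2, 4, 6)
  cells <- list()
  for (a in seq_along(ages)) for (i in seq_len(n_per_age)) {
    id <- sprintf("%s_%d", ages[a], i)
    cell <- make_test_cell(id, tau_k = tau_k[a] * (1 + 0.05 * (i - 1)),
                           r_mohm = r[a], hv1 = hv1[a], hth1 = hth1[a])
    cell$age <- ages[a]
    cal <- calibrate_scaling(cell$params, target_hz, dt = 1,
                             duration_ms = 5000, seed = seed + 10 * a + i)
    cell$scaling <- cal$scaling
    cell$rate_hz <- cal$rate_hz
    cells[[length(cells) + 1L]] <- cell
  }
  cell_pool(cells)
}

# brute-force O(n^2) coincidence count, the oracle for every coincidence-based
# statistic
brute_coincidences <- function(a, b, window) {
  if (!length(a$times) || !length(b$times)) return(0L)
  sum(abs(outer(a$times, b$times, "-")) <= window / 2)
}

poisson_train <- function(rate_hz, duration_ms, seed) {
  set.seed(seed)
  n <- stats::rpois(1, rate_hz * duration_ms / 1000)
  spike_train(sort(stats::runif(n, 0, duration_ms)), duration_ms)
}
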