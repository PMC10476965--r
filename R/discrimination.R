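#' Pattern-discrimination task configuration
#'
#' @param rho pair correlation (degree of separation); named levels of the
#'   task are low = 0.9997, medium = 0.999, high = 0.99 (see
#'   [separation_rho()]).
#' @param noise_level corruption fraction nu of each cell's stimulus copy.
#' @param n_pairs stimulus pairs per accuracy estimate (the task uses 200).
#' @param duration_ms stimulus duration (the task uses 10 s).
#' @param spikes_per_cell target spikes contributed per population member.
#' @param tau OU time constant (ms).
#' @param dt decoding grid step (ms).
#' @param seed RNG seed.
#' @return A `discrimination_config` list.
#' @export
discrimination_config <- function(rho = separation_rho("high"),
                                  noise_level = 0, n_pairs = 200,
                                  duration_ms = 10000,
                                  spikes_per_cell = 140, tau = 3, dt = 1,
                                  seed = 1) {
  stopifnot(rho >= 0, rho < 1, noise_level >= 0, noise_level < 1)
  structure(list(rho = rho, noise_level = noise_level, n_pairs = n_pairs,
                 duration_ms = duration_ms, spikes_per_cell = spikes_per_cell,
                 tau = tau, dt = dt, seed = seed),
            class = "discrimination_config")
}

#' Discriminate one correlated stimulus pair
#'
#' The first member of `pair` is encoded: every population member receives
#' its own independently corrupted copy of it (the corruption is unknown to
#' the decoder), scaled to its operating point; spikes are simulated and the
#' stimulus MAP-decoded under the clean OU model. The pair is discriminated
#' correctly when the reconstruction is closer (in MSE) to the encoded
#' stimulus than to its partner; exact ties count as incorrect.
#'
#' @param pool a [cell_pool()].
#' @param ids population member ids (repeats allowed).
#' @param pair list of two [stimulus_trace()]s; `pair[[1]]` is encoded.
#' @param cfg a [discrimination_config()].
#' @param pair_seed integer controlling corruption/simulation draws.
#' @param decode_cfg a [decode_config()].
#' @return List `correct` (logical), `mse_encoded`, `mse_other`, `r2`.
#' @export
discriminate_pair <- function(pool, ids, pair, cfg, pair_seed = 1,
                              decode_cfg = decode_config()) {
  eta1 <- pair[[1]]; eta2 <- pair[[2]]
  n <- eta1$n; dt <- eta1$dt
  prior <- prior_spec(cfg$tau, dt, n)
  T_s <- n * dt / 1000
  ou <- ou_spec(cfg$tau, dt, n * dt)
  entries <- lapply(seq_along(ids), function(pos) {
    cell <- pool_cell(pool, ids[pos])
    seed_c <- (pair_seed * 613L + pos * 31L) %% 2147483647L
    stim_c <- corrupt_stimulus(eta1, noise_spec(cfg$noise_level, seed = seed_c), ou)
    cur <- scale_stimulus(stim_c, cell$scaling)
    ntr <- equalize_trials(cell$rate_hz, T_s, cfg$spikes_per_cell)
    trains <- lapply(seq_len(ntr), function(tr)
      simulate_srm(cell$params, cur, seed = (seed_c + 7L * tr) %% 2147483647L)$spikes)
    list(params = cell$params, scaling = cell$scaling, trains = trains)
  })
  dec <- map_decode(encoder_bank(entries), prior, decode_cfg)
  mse1 <- mean((dec$eta_map - eta1$values)^2)
  mse2 <- mean((dec$eta_map - eta2$values)^2)
  list(correct = mse1 < mse2, mse_encoded = mse1, mse_other = mse2,
       r2 = r_squared(eta1$values, dec$eta_map))
}

#' Run the pattern-discrimination task
#'
#' Draws `n_pairs` independent correlated stimulus pairs, alternating which
#' member is encoded to cancel any construction asymmetry, and reports the
#' discrimination accuracy with its binomial standard error.
#'
#' @param pool a [cell_pool()].
#' @param ids population member ids.
#' @param cfg a [discrimination_config()].
#' @param decode_cfg a [decode_config()].
#' @return A `discrimination_result`: `accuracy`, `se`, `outcomes` (logical
#'   per pair), `mean_r2`.
#' @export
run_discrimination <- function(pool, ids, cfg = discrimination_config(),
                               decode_cfg = decode_config()) {
  stopifnot(inherits(cfg, "discrimination_config"))
  outcomes <- logical(cfg$n_pairs)
  r2s <- numeric(cfg$n_pairs)
  for (k in seq_len(cfg$n_pairs)) {
    base <- ou_spec(cfg$tau, cfg$dt, cfg$duration_ms,
                    seed = (cfg$seed + 29L * k) %% 2147483647L)
    pr <- sample_pair(pair_spec(cfg$rho, base))
    if (k %% 2L == 0L) pr <- rev(pr)  # alternate the encoded member
    out <- discriminate_pair(pool, ids, pr, cfg,
                             pair_seed = (cfg$seed + 101L * k) %% 2147483647L,
                             decode_cfg = decode_cfg)
    outcomes[k] <- out$correct
    r2s[k] <- out$r2
  }
  acc <- mean(outcomes)
  structure(list(accuracy = acc,
                 se = sqrt(acc * (1 - acc) / cfg$n_pairs),
                 outcomes = outcomes, mean_r2 = mean(r2s)),
            class = "discrimination_result")
}
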