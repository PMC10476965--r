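#' Pool of simulated cells
#'
#' @param cells list; each cell a list with `cell_id` (unique), `age` (one of
#'   `"4w"`, `"5w"`, `"mature"`), `params` ([srm_params()]), `scaling`
#'   ([scaling_spec()]) and `rate_hz` (> 0, under its calibrated current).
#' @return A `cell_pool` object.
#' @export
cell_pool <- function(cells) {
  ids <- vapply(cells, function(c) as.character(c$cell_id), character(1))
  if (anyDuplicated(ids)) stop("cell ids must be unique")
  rates <- vapply(cells, function(c) c$rate_hz, numeric(1))
  if (any(rates <= 0)) stop("rates must be positive")
  structure(list(cells = cells, ids = ids), class = "cell_pool")
}

pool_cell <- function(pool, id) pool$cells[[match(as.character(id), pool$ids)]]

#' Population decode: mean r-squared of a cell-id multiset
#'
#' Evaluates a population (repeats allowed) by decoding `length(stim_seeds)`
#' fresh OU stimuli from the joint spike trains of its members; each member
#' contributes `equalize_trials(rate, T, spikes_per_cell)` trials so every
#' cell's expected spike contribution matches. Simulation seeds are derived
#' deterministically from the stimulus seed and the member index, so
#' candidate comparisons can share stimuli (common random numbers).
#'
#' @param pool a [cell_pool()].
#' @param ids ordered cell ids of the population (repeats allowed).
#' @param duration_ms stimulus duration.
#' @param spikes_per_cell target expected spikes contributed per member.
#' @param stim_seeds integer seeds, one stimulus each.
#' @param tau,dt prior/grid parameters.
#' @param cfg a [decode_config()].
#' @param cache optional environment memoizing member spike trains per
#'   stimulus seed (used by the greedy search).
#' @return List `mean_r2`, `r2` (per stimulus), `info_bits`, `decodes`.
#' @export
evaluate_population <- function(pool, ids, duration_ms, spikes_per_cell,
                                stim_seeds, tau = 3, dt = 1,
                                cfg = decode_config(), cache = NULL) {
  n <- as.integer(round(duration_ms / dt))
  prior <- prior_spec(tau, dt, n)
  T_s <- duration_ms / 1000
  r2s <- numeric(length(stim_seeds))
  decs <- vector("list", length(stim_seeds))
  for (k in seq_along(stim_seeds)) {
    eta <- sample_ou(ou_spec(tau, dt, duration_ms, seed = stim_seeds[k]))
    entries <- lapply(seq_along(ids), function(pos) {
      cell <- pool_cell(pool, ids[pos])
      key <- sprintf("s%d_c%s_p%d", stim_seeds[k], cell$cell_id, pos)
      if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
      ntr <- equalize_trials(cell$rate_hz, T_s, spikes_per_cell)
      cur <- scale_stimulus(eta, cell$scaling)
      trains <- lapply(seq_len(ntr), function(tr)
        simulate_srm(cell$params, cur,
                     seed = (stim_seeds[k] * 131L + pos * 7L + tr) %% 2147483647L)$spikes)
      entry <- list(params = cell$params, scaling = cell$scaling, trains = trains)
      if (!is.null(cache)) cache[[key]] <- entry
      entry
    })
    dec <- map_decode(encoder_bank(entries), prior, cfg, eta_true = eta$values)
    r2s[k] <- dec$r2; decs[[k]] <- dec
  }
  list(mean_r2 = mean(r2s), r2 = r2s,
       info_bits = mutual_information(decs, prior), decodes = decs)
}

#' Greedy construction of a decoding-optimized population
#'
#' Starts from a given cell and, at each step, extends the population with
#' the candidate (chosen with replacement from the pool, optionally
#' restricted to mature cells for the first steps) whose addition yields the
#' largest mean reconstruction r-squared over shared fresh stimuli. Ties go
#' to the lowest cell id and are logged in the result.
#'
#' @param pool a [cell_pool()].
#' @param start_id id of the first member.
#' @param K final population size.
#' @param spikes_per_cell target spikes contributed per member (the
#'   population protocol uses 1200 on average).
#' @param repeats stimuli evaluated per candidate (common across candidates).
#' @param duration_ms stimulus duration.
#' @param mature_only_steps candidates restricted to mature cells for this
#'   many initial steps (0 = unconstrained).
#' @param tau,dt,cfg decoding parameters.
#' @param seed seed for the per-step stimulus draws.
#' @return A `population_selection`: `ids` (ordered members), `step_r2`,
#'   `step_info`, `ties` (count), `trial_counts` (per member).
#' @export
greedy_build <- function(pool, start_id, K, spikes_per_cell = 1200,
                         repeats = 5, duration_ms = 2000,
                         mature_only_steps = 0, tau = 3, dt = 1,
                         cfg = decode_config(), seed = 1) {
  stopifnot(inherits(pool, "cell_pool"), K >= 1)
  if (!as.character(start_id) %in% pool$ids) stop("start cell not in pool")
  if (mature_only_steps > K) stop("mature_only_steps cannot exceed K")
  ages <- vapply(pool$cells, `[[`, character(1), "age")
  ids <- as.character(start_id)
  step_r2 <- numeric(K); step_info <- numeric(K); ties <- 0L
  stim_seeds0 <- (seed + seq_len(repeats)) %% 2147483647L
  ev1 <- evaluate_population(pool, ids, duration_ms, spikes_per_cell,
                             stim_seeds0, tau, dt, cfg)
  step_r2[1] <- ev1$mean_r2; step_info[1] <- ev1$info_bits
  for (step in seq_len(K - 1L)) {
    stim_seeds <- (seed + 1000L * step + seq_len(repeats)) %% 2147483647L
    candidates <- if (step + 1L <= mature_only_steps) pool$ids[ages == "mature"] else pool$ids
    cache <- new.env(parent = emptyenv())
    scores <- vapply(candidates, function(cid) {
      evaluate_population(pool, c(ids, cid), duration_ms, spikes_per_cell,
                          stim_seeds, tau, dt, cfg, cache = cache)$mean_r2
    }, numeric(1))
    best <- max(scores)
    winners <- candidates[scores >= best - 1e-12]
    if (length(winners) > 1L) ties <- ties + 1L
    pick <- winners[order(winners)][1L]
    ids <- c(ids, pick)
    ev <- evaluate_population(pool, ids, duration_ms, spikes_per_cell,
                              stim_seeds, tau, dt, cfg, cache = cache)
    step_r2[step + 1L] <- ev$mean_r2
    step_info[step + 1L] <- ev$info_bits
  }
  T_s <- duration_ms / 1000
  trial_counts <- vapply(ids, function(cid)
    equalize_trials(pool_cell(pool, cid)$rate_hz, T_s, spikes_per_cell), integer(1))
  structure(list(ids = ids, step_r2 = step_r2, step_info = step_info,
                 ties = ties, trial_counts = trial_counts,
                 mature_only_steps = mature_only_steps),
            class = "population_selection")
}

#' Constrained greedy selection (mature-only initial steps)
#'
#' Convenience wrapper over [greedy_build()] restricting the candidate set to
#' mature cells for the first `mature_only_steps` steps; with
#' `mature_only_steps = 0` it is identical to the unconstrained procedure
#' under the same seeds.
#'
#' @inheritParams greedy_build
#' @return A `population_selection`.
#' @export
constrained_greedy <- function(pool, start_id, K, mature_only_steps,
                               spikes_per_cell = 1200, repeats = 5,
                               duration_ms = 2000, tau = 3, dt = 1,
                               cfg = decode_config(), seed = 1) {
  greedy_build(pool, start_id, K, spikes_per_cell, repeats, duration_ms,
               mature_only_steps, tau, dt, cfg, seed)
}

#' Random-selection baseline
#'
#' Populations of sizes 1..K drawn uniformly with replacement; mean
#' r-squared and information per size, for comparison against the greedy
#' populations.
#'
#' @param pool a [cell_pool()].
#' @param K maximum population size.
#' @param n_pops number of random populations.
#' @param spikes_per_cell,repeats,duration_ms,tau,dt,cfg as in [greedy_build()].
#' @param seed RNG seed.
#' @param decode if FALSE, only the selections are drawn (no decoding).
#' @return List `selections` (list of id vectors) and, when decoded,
#'   `mean_r2`/`mean_info` (per size, averaged over populations).
#' @export
random_baseline <- function(pool, K, n_pops, spikes_per_cell = 1200,
                            repeats = 3, duration_ms = 2000, tau = 3, dt = 1,
                            cfg = decode_config(), seed = 1, decode = TRUE) {
  set.seed(seed)
  selections <- lapply(seq_len(n_pops), function(i)
    sample(pool$ids, K, replace = TRUE))
  out <- list(selections = selections)
  if (decode) {
    r2 <- info <- matrix(NA_real_, n_pops, K)
    for (i in seq_len(n_pops)) {
      stim_seeds <- (seed + 500L * i + seq_len(repeats)) %% 2147483647L
      cache <- new.env(parent = emptyenv())
      for (k in seq_len(K)) {
        ev <- evaluate_population(pool, selections[[i]][seq_len(k)],
                                  duration_ms, spikes_per_cell, stim_seeds,
                                  tau, dt, cfg, cache = cache)
        r2[i, k] <- ev$mean_r2; info[i, k] <- ev$info_bits
      }
    }
    out$r2 <- r2; out$info <- info
    out$mean_r2 <- colMeans(r2); out$mean_info <- colMeans(info)
  }
  out
}

#' Census of greedy selections
#'
#' Tallies how many times each cell was selected across populations, the
#' per-step age fractions, and the cumulative age fractions by population
#' size.
#'
#' @param selections list of id vectors (ordered populations), or of
#'   `population_selection` objects.
#' @param pool a [cell_pool()] (for ages and the full id universe).
#' @return List `counts` (named per cell, zero-filled), `step_age_fraction`
#'   (steps x ages), `cumulative_age_fraction` (sizes x ages),
#'   `total_selections`.
#' @export
selection_census <- function(selections, pool) {
  sels <- lapply(selections, function(s) if (inherits(s, "population_selection")) s$ids else as.character(s))
  ages <- stats::setNames(vapply(pool$cells, `[[`, character(1), "age"), pool$ids)
  age_levels <- c("4w", "5w", "mature")
  counts <- stats::setNames(numeric(length(pool$ids)), pool$ids)
  tab <- table(unlist(sels))
  counts[names(tab)] <- as.numeric(tab)
  K <- max(lengths(sels))
  step_frac <- matrix(0, K, length(age_levels),
                      dimnames = list(NULL, age_levels))
  for (k in seq_len(K)) {
    at_k <- unlist(lapply(sels, function(s) if (length(s) >= k) ages[[s[k]]]))
    tf <- table(factor(at_k, levels = age_levels))
    step_frac[k, ] <- as.numeric(tf) / max(1, length(at_k))
  }
  cum_frac <- apply(step_frac, 2, cumsum) / seq_len(K)
  list(counts = counts, step_age_fraction = step_frac,
       cumulative_age_fraction = cum_frac,
       total_selections = sum(lengths(sels)))
}

#' Bootstrap relative reconstruction MSE between two population groups
#'
#' Resamples populations with replacement from each group and, per population
#' size, forms the ratio of group-mean reconstruction MSEs (group A over
#' group B, so a ratio below 1 means group A reconstructs better); reports
#' the mean ratio and a symmetric 95% percentile confidence interval.
#'
#' @param mseA,mseB matrices (populations x sizes) of reconstruction MSE,
#'   evaluated on common stimulus seeds.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return List `ratio` (per size), `ci_lower`, `ci_upper`.
#' @export
relative_mse_bootstrap <- function(mseA, mseB, n_boot = 1000, seed = 1) {
  stopifnot(ncol(mseA) == ncol(mseB))
  set.seed(seed)
  K <- ncol(mseA)
  boots <- matrix(NA_real_, n_boot, K)
  for (b in seq_len(n_boot)) {
    ia <- sample(nrow(mseA), replace = TRUE)
    ib <- sample(nrow(mseB), replace = TRUE)
    boots[b, ] <- colMeans(mseA[ia, , drop = FALSE]) /
      colMeans(mseB[ib, , drop = FALSE])
  }
  list(ratio = colMeans(boots),
       ci_lower = apply(boots, 2, stats::quantile, 0.025),
       ci_upper = apply(boots, 2, stats::quantile, 0.975))
}
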