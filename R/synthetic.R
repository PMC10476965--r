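#' Age-cohort specification for synthetic granule cells
#'
#' Ground-truth parameter distributions emulating the maturation trends seen
#' in the recordings: adult-born (4-week) cells integrate over longer
#' timescales (larger membrane-filter time constant and resistance) and show
#' weaker post-spike effects (smaller |h_v| kick and smaller threshold
#' deflection) than mature cells. Centers are design choices reproducing the
#' orderings, not measured values.
#'
#' @param ages cohort labels, oldest last.
#' @param n_cells cells per cohort (the study pool is 20/17/18 for
#'   4w/5w/mature).
#' @param tau_k_ms membrane-filter tail time constant centers per cohort.
#' @param resistance_mohm filter-area resistance centers per cohort.
#' @param hv1_mv first post-spike voltage-filter amplitude centers (mV,
#'   negative: after-hyperpolarizing kick).
#' @param hth1_mv first threshold-filter amplitude centers (mV, positive:
#'   refractory).
#' @param vth_mv static threshold centers (mV).
#' @param vb_mv voltage bias (resting potential held near -70 mV).
#' @param delta_v_mv voltage-scale centers (mV).
#' @param cv lognormal dispersion (coefficient of variation) of the positive
#'   parameters.
#' @param target_rate_hz firing rate the per-cell current scaling is
#'   calibrated to.
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(ages = c("4w", "5w", "mature"),
                        n_cells = c(20L, 17L, 18L),
                        tau_k_ms = c(55, 40, 25),
                        resistance_mohm = c(450, 350, 250),
                        hv1_mv = c(-0.5, -1.5, -3),
                        hth1_mv = c(2, 4, 6),
                        vth_mv = c(-52, -51, -50),
                        vb_mv = -70,
                        delta_v_mv = c(1.5, 1.2, 1.0),
                        cv = 0.12,
                        target_rate_hz = 2,
                        seed = 1) {
  stopifnot(length(ages) == length(n_cells),
            all(diff(tau_k_ms) < 0), all(diff(resistance_mohm) < 0),
            all(diff(hv1_mv) < 0), all(diff(hth1_mv) > 0),
            cv > 0, target_rate_hz > 0)
  structure(list(ages = ages, n_cells = as.integer(n_cells),
                 tau_k_ms = tau_k_ms, resistance_mohm = resistance_mohm,
                 hv1_mv = hv1_mv, hth1_mv = hth1_mv, vth_mv = vth_mv,
                 vb_mv = vb_mv, delta_v_mv = delta_v_mv, cv = cv,
                 target_rate_hz = target_rate_hz, seed = seed),
            class = "cohort_spec")
}

# lognormal draw with given mean and coefficient of variation
rlnorm_cv <- function(n, mean, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

# ground-truth filters on the given bases from scalar summaries
build_cell_params <- function(tau_k, r_mohm, hv1, hth1, vth, vb, delta_v,
                              bases, cell_id) {
  tk <- bases$k
  centers_k <- tk$start + (seq_len(tk$n_bins) - 0.5) * tk$width
  shape <- exp(-centers_k / tau_k)
  # scale the exponential so the filter area matches the target resistance
  kc <- shape * (r_mohm / 1000) / (sum(shape) * tk$width)
  th <- bases$hv
  centers_hv <- th$start + (seq_len(th$n_bins) - 0.5) * th$width
  hv <- hv1 * exp(-(centers_hv - centers_hv[1]) / 100)
  tt <- bases$hth
  centers_hth <- tt$start + (seq_len(tt$n_bins) - 0.5) * tt$width
  hth <- hth1 * exp(-(centers_hth - centers_hth[1]) / 50)
  srm_params(vb, kc, hv, vth, hth, delta_v, bases = bases, cell_id = cell_id)
}

#' Calibrate the current scaling of a cell to a target rate
#'
#' Bisection on the mean current mu (with sigma fixed at 0.5 mu, mirroring
#' the experimental practice of adapting baseline and amplitude per cell)
#' until the simulated firing rate is within `tol_frac` of the target.
#' A fixed calibration stimulus (common random numbers) keeps the
#' rate-vs-mu map deterministic.
#'
#' @param p an [srm_params()].
#' @param target_hz target firing rate.
#' @param dt simulation step (ms).
#' @param duration_ms calibration stimulus duration.
#' @param tau OU time constant (ms).
#' @param tol_frac relative rate tolerance.
#' @param seed seed of the calibration stimulus and simulations.
#' @param max_iter bisection iterations.
#' @return List `scaling` ([scaling_spec()]) and `rate_hz` (achieved).
#' @export
calibrate_scaling <- function(p, target_hz, dt = 1, duration_ms = 20000,
                              tau = 3, tol_frac = 0.1, seed = 1,
                              max_iter = 40) {
  eta <- sample_ou(ou_spec(tau, dt, duration_ms, seed = seed))
  rate_at <- function(mu) {
    cur <- scale_stimulus(eta, scaling_spec(mu, 0.5 * mu))
    rec <- simulate_srm(p, cur, seed = seed + 1L)
    1000 * n_spikes(rec$spikes) / duration_ms
  }
  # bracket: the rate is increasing in mu for these cells
  lo <- 0; hi <- 2 * (p$vth - p$vb) / (filter_resistance(p) / 1000)
  it <- 0
  while (rate_at(hi) < target_hz && it < 12) { hi <- hi * 1.6; it <- it + 1 }
  if (rate_at(hi) < target_hz)
    stop("calibration failed: cannot reach the target rate")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target_hz) <= tol_frac * target_hz)
      return(list(scaling = scaling_spec(mid, 0.5 * mid), rate_hz = r))
    if (r < target_hz) lo <- mid else hi <- mid
  }
  r <- rate_at((lo + hi) / 2)
  if (r < 0.5 || r > 10)
    stop(sprintf("calibration failed: rate %.2f Hz outside [0.5, 10] Hz", r))
  list(scaling = scaling_spec((lo + hi) / 2, 0.5 * (lo + hi) / 2), rate_hz = r)
}

#' Sample a synthetic age-structured cell pool
#'
#' Draws per-cell SRM parameters from the cohort distributions (lognormal for
#' positive scale parameters, normal for voltages), builds the three filters
#' on the default bases, and calibrates each cell's current scaling to the
#' target rate. Cohort means of the drawn time constants preserve the
#' specified age ordering by construction; the draw is redone (new substream)
#' in the rare case sampling noise breaks the ordering.
#'
#' @param spec a [cohort_spec()].
#' @param bases filter bases for all cells.
#' @param calib_dt,calib_duration_ms calibration grid (see
#'   [calibrate_scaling()]).
#' @return A [cell_pool()]; each cell carries `truth` (the scalar summaries
#'   it was built from).
#' @export
sample_cohort <- function(spec, bases = default_bases(), calib_dt = 1,
                          calib_duration_ms = 20000) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (attempt in 0:4) {
    set.seed(spec$seed + attempt)
    cells <- list()
    mean_tau <- numeric(length(spec$ages))
    for (a in seq_along(spec$ages)) {
      na <- spec$n_cells[a]
      tau_k <- rlnorm_cv(na, spec$tau_k_ms[a], spec$cv)
      r_in <- rlnorm_cv(na, spec$resistance_mohm[a], spec$cv)
      hv1 <- -rlnorm_cv(na, -spec$hv1_mv[a], spec$cv)
      hth1 <- rlnorm_cv(na, spec$hth1_mv[a], spec$cv)
      vth <- stats::rnorm(na, spec$vth_mv[a], 1)
      dv <- rlnorm_cv(na, spec$delta_v_mv[a], spec$cv)
      mean_tau[a] <- mean(tau_k)
      for (i in seq_len(na)) {
        id <- sprintf("%s_%02d", spec$ages[a], i)
        cells[[length(cells) + 1L]] <-
          list(cell_id = id, age = spec$ages[a],
               truth = list(tau_k = tau_k[i], resistance = r_in[i],
                            hv1 = hv1[i], hth1 = hth1[i], vth = vth[i],
                            delta_v = dv[i]),
               params = build_cell_params(tau_k[i], r_in[i], hv1[i], hth1[i],
                                          vth[i], spec$vb_mv, dv[i], bases, id))
      }
    }
    present <- spec$n_cells > 0
    if (all(diff(mean_tau[present]) < 0)) break
  }
  for (ci in seq_along(cells)) {
    cal <- calibrate_scaling(cells[[ci]]$params, spec$target_rate_hz,
                             dt = calib_dt, duration_ms = calib_duration_ms,
                             seed = spec$seed + 37L * ci)
    cells[[ci]]$scaling <- cal$scaling
    cells[[ci]]$rate_hz <- cal$rate_hz
  }
  cell_pool(cells)
}

#' Recording protocol specification
#'
#' The study's protocol: one 99 s single-trial training recording and nine
#' repeated 10 s validation trials per cell, at 10 kHz, with optional
#' Gaussian voltage observation noise.
#'
#' @param train_duration_ms training recording length.
#' @param n_validation validation trials.
#' @param validation_duration_ms validation trial length.
#' @param dt grid step (ms).
#' @param voltage_noise_mv observation-noise sd added to voltages.
#' @param tau OU stimulus time constant (ms).
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(train_duration_ms = 99000, n_validation = 9,
                          validation_duration_ms = 10000, dt = 0.1,
                          voltage_noise_mv = 0.3, tau = 3) {
  structure(list(train_duration_ms = train_duration_ms,
                 n_validation = n_validation,
                 validation_duration_ms = validation_duration_ms,
                 dt = dt, voltage_noise_mv = voltage_noise_mv, tau = tau),
            class = "protocol_spec")
}

#' Synthesize a full recording protocol for a cell pool
#'
#' One independent training stimulus per cell; a single validation stimulus
#' template shared by all cells (scaled to each cell's operating point, as in
#' the experiment) presented over repeated trials. Voltages carry optional
#' Gaussian observation noise; the returned spike times are the generative
#' ones.
#'
#' @param pool a [cell_pool()].
#' @param protocol a [protocol_spec()].
#' @param seed RNG seed.
#' @return Named list per cell id: `train` (a [recording()]) and
#'   `validation` (list of [recording()]s).
#' @export
synthesize_recordings <- function(pool, protocol = protocol_spec(), seed = 1) {
  stopifnot(inherits(pool, "cell_pool"), inherits(protocol, "protocol_spec"))
  val_template <- sample_ou(ou_spec(protocol$tau, protocol$dt,
                                    protocol$validation_duration_ms,
                                    seed = seed))
  out <- list()
  for (ci in seq_along(pool$cells)) {
    cell <- pool$cells[[ci]]
    train_eta <- sample_ou(ou_spec(protocol$tau, protocol$dt,
                                   protocol$train_duration_ms,
                                   seed = seed + 1000L + ci))
    train_cur <- scale_stimulus(train_eta, cell$scaling)
    train <- simulate_srm(cell$params, train_cur, seed = seed + 2000L + ci)
    train$cell_id <- cell$cell_id
    val_cur <- scale_stimulus(val_template, cell$scaling)
    validation <- lapply(seq_len(protocol$n_validation), function(tr) {
      rec <- simulate_srm(cell$params, val_cur,
                          seed = seed + 3000L + 100L * ci + tr)
      rec$cell_id <- cell$cell_id; rec$trial_id <- tr
      rec
    })
    if (protocol$voltage_noise_mv > 0) {
      set.seed(seed + 4000L + ci)
      train$voltage <- train$voltage +
        stats::rnorm(length(train$voltage), 0, protocol$voltage_noise_mv)
      for (tr in seq_along(validation))
        validation[[tr]]$voltage <- validation[[tr]]$voltage +
          stats::rnorm(length(validation[[tr]]$voltage), 0,
                       protocol$voltage_noise_mv)
    }
    out[[cell$cell_id]] <- list(train = train, validation = validation)
  }
  out
}

#' Load deposited intracellular recordings
#'
#' Optional loader for a user-supplied download of the study's deposited
#' current-clamp dataset, exported as plain text: one directory per cell
#' containing `train_stimulus.csv`/`train_voltage.csv` and
#' `valid<k>_stimulus.csv`/`valid<k>_voltage.csv` two-column (time_ms, value)
#' files at 10 kHz, currents in pA and voltages in mV. Spikes are extracted
#' by threshold crossing. Nothing else in the package depends on this data.
#'
#' @param path directory of the exported dataset.
#' @param threshold_mv spike-detection threshold.
#' @return Named list per cell: `train`, `validation` ([recording()]s).
#' @export
load_real <- function(path, threshold_mv = 0) {
  if (!dir.exists(path))
    stop("real-data directory not found: ", path,
         " (supply a local export of the deposited dataset)")
  cells <- list.dirs(path, recursive = FALSE)
  if (!length(cells)) stop("no cell directories under ", path)
  out <- list()
  for (cd in cells) {
    id <- basename(cd)
    read_rec <- function(stem, trial_id = NULL) {
      sf <- file.path(cd, paste0(stem, "_stimulus.csv"))
      vf <- file.path(cd, paste0(stem, "_voltage.csv"))
      if (!file.exists(sf) || !file.exists(vf))
        stop("unknown layout in ", cd, ": missing ", stem, " files")
      stim <- read_stimulus_csv(sf)
      volt <- read_stimulus_csv(vf)$values
      spikes <- detect_spikes(volt, stim$dt, threshold_mv)
      recording(stim, volt, spikes, cell_id = id, trial_id = trial_id)
    }
    train <- read_rec("train")
    vfiles <- sort(list.files(cd, pattern = "^valid[0-9]+_stimulus\\.csv$"))
    validation <- lapply(seq_along(vfiles), function(k)
      read_rec(sub("_stimulus\\.csv$", "", vfiles[k]), trial_id = k))
    out[[id]] <- list(train = train, validation = validation)
  }
  out
}
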