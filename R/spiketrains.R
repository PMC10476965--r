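#' Spike train container
#'
#' Sorted spike times (ms) over a recording of duration `duration` (ms).
#'
#' @param times numeric vector of spike times in ms, strictly increasing,
#'   each in `[0, duration)`.
#' @param duration recording duration in ms.
#' @return An object of class `spike_train` with fields `times`, `duration`.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  if (length(times)) {
    if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
    if (min(times) < 0 || max(times) >= duration)
      stop("spike times must lie in [0, duration)")
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3g s (%.2f Hz)\n",
              length(x$times), x$duration / 1000,
              1000 * length(x$times) / x$duration))
  invisible(x)
}

#' Number of spikes in a train
#' @param s a [spike_train()].
#' @return Integer spike count.
#' @export
n_spikes <- function(s) length(s$times)

#' Trial set: repeated responses to one stimulus
#'
#' @param trains list of [spike_train()] objects sharing one duration.
#' @param stimulus_id optional identifier of the eliciting stimulus.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trains, stimulus_id = NULL) {
  stopifnot(length(trains) >= 1L,
            all(vapply(trains, inherits, logical(1), "spike_train")))
  durs <- vapply(trains, function(s) s$duration, numeric(1))
  if (max(durs) - min(durs) > 1e-9) stop("all trials must share one duration")
  structure(list(trains = trains, duration = durs[1],
                 M = length(trains), stimulus_id = stimulus_id),
            class = "trial_set")
}

#' Mean spike count N(S) over the trials of a set
#' @param A a [trial_set()].
#' @return Average number of spikes per trial.
#' @export
mean_spike_count <- function(A) {
  mean(vapply(A$trains, n_spikes, numeric(1)))
}

#' Write / read spike trains as plain text, one train per line
#'
#' Each line holds the spike times of one train in ms, space-separated; the
#' first line is a comment carrying the common duration.
#'
#' @param A a [trial_set()].
#' @param path file path.
#' @return `read_trains_txt` returns a [trial_set()].
#' @export
write_trains_txt <- function(A, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_ms=%.17g", A$duration), con)
  for (s in A$trains)
    writeLines(paste(sprintf("%.17g", s$times), collapse = " "), con)
  invisible(path)
}

#' @rdname write_trains_txt
#' @export
read_trains_txt <- function(path) {
  lines <- readLines(path)
  duration <- as.numeric(sub(".*duration_ms=(\\S+).*", "\\1", lines[1]))
  trains <- lapply(lines[-1], function(l) {
    ts <- if (nzchar(trimws(l))) as.numeric(strsplit(trimws(l), "\\s+")[[1]]) else numeric(0)
    spike_train(ts, duration)
  })
  trial_set(trains)
}
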