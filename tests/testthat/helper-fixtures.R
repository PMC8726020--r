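# Fixtures and independent oracles shared across the suite.  Everything is
# generated in code; no binary fixtures.

# Noise-free generator settings: templates only, so feature extractors can
# be checked against the exact generating values.
quiet_params <- function(...) {
  synth_params(noise_sd_accel = 0, noise_sd_gyro = 0, idle_sway_amp = 0, ...)
}

# A deliberately small detector for unit tests of the training machinery.
tiny_detector_config <- function(...) {
  defaults <- list(conv_filters = 4L, lstm_units = 6L,
                   dense_sizes = c(8L, 4L, 2L), batch_size = 64L,
                   early_stop_patience_epochs = 5L, max_epochs = 15L,
                   train_step_s = 0.1, seed = 7L)
  do.call(detector_config, utils::modifyList(defaults, list(...)))
}

# Deterministic recording: constant-rate time grid with supplied channels.
make_recording <- function(accel, gyro, fs = 40, task = "sit_to_stand",
                           subject_id = "T01") {
  n <- ncol(accel)
  imu_recording(subject_id, task, (seq_len(n) - 1) / fs, accel, gyro,
                sampling_rate_hz = fs)
}

# Linearly separable toy window set: task windows have amplitude `amp` in
# every channel, nontask windows are zero, plus small seeded jitter.
toy_window_set <- function(n_task = 60L, n_nontask = 60L, w = 12L,
                           amp = 1, seed = 1L) {
  set.seed(seed)
  n <- n_task + n_nontask
  x <- array(stats::rnorm(n * w * 6, sd = 0.05), dim = c(n, w, 6))
  x[seq_len(n_task), , ] <- x[seq_len(n_task), , ] + amp
  p_task <- rep(c(1, 0), c(n_task, n_nontask))
  structure(list(x = x, center_time_s = seq_len(n) * 0.025,
                 start_time_s = seq_len(n) * 0.025, window_s = w / 40,
                 step_s = 0.025, sampling_rate_hz = 40,
                 soft_labels = cbind(p_task = p_task, p_nontask = 1 - p_task)),
            class = "window_set")
}

# Independent literal implementation of the candidate-interval rules,
# written as plain index scans (no rle, no cumsum) for oracle comparison.
brute_local_maxima <- function(x, min_height, min_sep) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        cand <- c(cand, i + (j - i) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  cand <- cand[x[cand] >= min_height]
  if (length(cand) <= 1L || min_sep <= 1L) return(cand)
  keep <- integer(0)
  remaining <- cand[order(-x[cand], cand)]
  for (p in remaining) {
    ok <- TRUE
    for (q in keep) if (abs(p - q) < min_sep) ok <- FALSE
    if (ok) keep <- c(keep, p)
  }
  sort(keep)
}

brute_candidates <- function(trace, prob_threshold = 0.5, peak_height = 0.5,
                             min_sep_s = 0.25) {
  times <- trace$center_times_s
  step <- stats::median(diff(times))
  min_sep <- max(1L, as.integer(round(min_sep_s / step)))
  peaks <- brute_local_maxima(trace$p_nontask, peak_height, min_sep)
  n <- length(times)
  above <- trace$p_task > prob_threshold
  out <- list()
  prev_end <- -Inf
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      s <- i
      while (i <= n && above[i]) i <- i + 1L
      e <- i - 1L
      before <- peaks[peaks < s]; after <- peaks[peaks > e]
      degen <- FALSE
      start_t <- if (length(before)) times[before[length(before)]] else {
        degen <- TRUE; times[s]
      }
      end_t <- if (length(after)) times[after[1L]] else {
        degen <- TRUE; times[e]
      }
      if (start_t < prev_end) start_t <- prev_end
      if (start_t < end_t) {
        prev_end <- end_t
        out[[length(out) + 1L]] <- c(start = start_t, end = end_t,
                                     degen = as.numeric(degen))
      }
    } else i <- i + 1L
  }
  out
}

# Exhaustive pair-counting AUC oracle (ties contribute 1/2).
brute_auc <- function(scores, labels) {
  pos <- which(labels == "deviating"); neg <- which(labels == "normal")
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Random plausible probability trace for oracle comparisons: a smoothed
# random walk squashed to (0, 1).
random_trace <- function(n, seed) {
  set.seed(seed)
  z <- cumsum(stats::rnorm(n, sd = 0.4))
  z <- stats::filter(z, rep(1 / 5, 5), sides = 2)
  z[is.na(z)] <- 0
  p <- stats::plogis(as.numeric(z))
  probability_trace((seq_len(n) - 1) * 0.025, p, 1 - p)
}
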