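# Seeded synthetic recordings emulating the three balance tasks, standing in
# for the undeposited 59-subject community cohort.  Templates are parametric
# (raised-cosine acceleration pulses, trapezoidal yaw velocity), not
# resampled human data, so the generating values are known exactly and the
# feature extractors can be validated against them.

#' Synthetic-cohort generation parameters
#'
#' Defaults emulate the study conditions: idle (nontask) padding of 2-6 s
#' before and 1-3 s after the task, sit/stand transition durations of
#' 1.5-3.5 s with biphasic anterior-posterior thrust pulses of 1.5-2.5
#' m/s^2, turning speeds drawn per condition from truncated normals matching
#' the reported cohort feature distributions (healthy 58.16 (SD 19.22)
#' deg/s on [20, 100]; deviating 23.46 (SD 13.96) deg/s on [8, 60]), attempt
#' (peak-count) tables per task and condition matching the reported
#' peak-count means, white sensor noise (accelerometer SD 0.05 m/s^2,
#' gyroscope SD 1 deg/s), and a 0.1 m/s^2 idle postural sway.
#'
#' @param pre_idle_s,post_idle_s Uniform ranges (s) of nontask padding.
#' @param task_duration_s Uniform range (s) of sit/stand transition duration.
#' @param ap_pulse_amp Uniform range (m/s^2) of the main AP pulse amplitude.
#' @param attempts Per-task, per-condition probability tables over attempt
#'   counts; names are peak counts, values probabilities summing to 1.
#' @param turn_speed Per-condition truncated-normal specs
#'   (`mean`, `sd`, `min`, `max`) of the average turning speed in deg/s.
#' @param turn_ramp_frac Fraction of the turn spent in each velocity ramp of
#'   the trapezoidal yaw profile (default 0.15).
#' @param turn_pause If `TRUE`, deviating turning recordings include a
#'   mid-turn pause (yaw velocity dips to zero for 0.3-1 s), emulating
#'   failures of the "turns 360 degrees continuously" grading item.
#'   Off by default.
#' @param noise_sd_accel,noise_sd_gyro White-noise SDs (m/s^2, deg/s).
#' @param idle_sway_amp Amplitude (m/s^2) of the slow sinusoidal postural
#'   sway present throughout the recording.
#' @param sampling_rate_hz Sampling rate (default 40).
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(pre_idle_s = c(2, 6), post_idle_s = c(1, 3),
                         task_duration_s = c(1.5, 3.5),
                         ap_pulse_amp = c(1.5, 2.5),
                         attempts = list(
                           sit_to_stand = list(
                             normal = c("1" = 0.95, "2" = 0.05),
                             deviating = c("1" = 0.20, "2" = 0.40,
                                           "3" = 0.25, "4" = 0.15)),
                           stand_to_sit = list(
                             normal = c("1" = 0.97, "2" = 0.03),
                             deviating = c("1" = 0.35, "2" = 0.50,
                                           "3" = 0.15))),
                         turn_speed = list(
                           normal = list(mean = 58.16, sd = 19.22,
                                         min = 20, max = 100),
                           deviating = list(mean = 23.46, sd = 13.96,
                                            min = 8, max = 60)),
                         turn_ramp_frac = 0.15, turn_pause = FALSE,
                         noise_sd_accel = 0.05, noise_sd_gyro = 1,
                         idle_sway_amp = 0.1, sampling_rate_hz = 40) {
  p <- structure(
    list(pre_idle_s = pre_idle_s, post_idle_s = post_idle_s,
         task_duration_s = task_duration_s, ap_pulse_amp = ap_pulse_amp,
         attempts = attempts, turn_speed = turn_speed,
         turn_ramp_frac = turn_ramp_frac, turn_pause = isTRUE(turn_pause),
         noise_sd_accel = noise_sd_accel, noise_sd_gyro = noise_sd_gyro,
         idle_sway_amp = idle_sway_amp, sampling_rate_hz = sampling_rate_hz),
    class = "synth_params")
  validate_synth_params(p)
}

validate_synth_params <- function(p) {
  stopifnot(inherits(p, "synth_params"))
  for (f in c("pre_idle_s", "post_idle_s", "task_duration_s", "ap_pulse_amp")) {
    r <- p[[f]]
    if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2]) {
      stop(f, " must be a positive range c(lo, hi)")
    }
  }
  for (task in names(p$attempts)) {
    for (cond in names(p$attempts[[task]])) {
      tab <- p$attempts[[task]][[cond]]
      check_prob_table(tab, paste0("attempts$", task, "$", cond))
    }
  }
  for (cond in c("normal", "deviating")) {
    ts <- p$turn_speed[[cond]]
    if (is.null(ts) || !all(c("mean", "sd", "min", "max") %in% names(ts))) {
      stop("turn_speed$", cond, " must list mean, sd, min, max")
    }
    if (ts$sd < 0 || ts$min <= 0 || ts$max < ts$min) {
      stop("turn_speed$", cond, " is malformed")
    }
  }
  if (p$turn_ramp_frac < 0 || p$turn_ramp_frac >= 0.5) {
    stop("turn_ramp_frac must lie in [0, 0.5)")
  }
  if (p$noise_sd_accel < 0 || p$noise_sd_gyro < 0 || p$idle_sway_amp < 0) {
    stop("noise and sway amplitudes must be non-negative")
  }
  if (p$sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  p
}

check_prob_table <- function(tab, what) {
  if (length(tab) == 0L || is.null(names(tab))) {
    stop(what, ": probability table must be a named vector")
  }
  if (any(tab < 0) || all(tab == 0)) {
    stop(what, ": probabilities must be non-negative with positive total")
  }
  if (abs(sum(tab) - 1) > 1e-8) stop(what, ": probabilities must sum to 1")
  counts <- suppressWarnings(as.integer(names(tab)))
  if (anyNA(counts) || any(counts < 0)) {
    stop(what, ": table names must be non-negative integer counts")
  }
  invisible(tab)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

# Truncated-normal draws by rejection; degenerate SD returns the clipped mean.
rtruncnorm <- function(n, mean, sd, min, max) {
  if (sd <= 0) return(rep(pmin(pmax(mean, min), max), n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw >= min & draw <= max])
  }
  out[seq_len(n)]
}

# Raised-cosine (Hann) lobe of unit amplitude on [0, 1].
hann_lobe <- function(u) ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)

draw_attempt_count <- function(tab) {
  counts <- as.integer(names(tab))
  counts[sample.int(length(tab), 1L, prob = tab)]
}

# Biphasic AP thrust template over `n` samples: `k` positive raised-cosine
# pulses (one per equal slot, first at the drawn main amplitude, later
# attempts at 60-100 % of it) each followed by a smaller negative rebound
# lobe.  All positive peaks clear the 45 % relative threshold by design.
ap_pulse_train <- function(n, k, main_amp) {
  sig <- numeric(n)
  slot <- n / k
  for (i in seq_len(k)) {
    amp <- if (i == 1L) main_amp else main_amp * stats::runif(1, 0.6, 1.0)
    i0 <- round((i - 1) * slot)
    len <- floor(slot)
    u <- (seq_len(len) - 0.5) / len
    pos <- hann_lobe(u / 0.6)            # positive lobe on first 60 %
    neg <- hann_lobe((u - 0.6) / 0.4)    # rebound on final 40 %
    sig[i0 + seq_len(len)] <- amp * pos - 0.4 * amp * neg
  }
  sig
}

# Trapezoidal yaw-velocity profile over `n` samples at rate `fs` whose
# rectangle-rule integral is exactly `total_deg`.
trapezoid_yaw <- function(n, fs, total_deg, ramp_frac) {
  u <- (seq_len(n) - 0.5) / n
  shape <- pmin(1, pmin(u, 1 - u) / max(ramp_frac, 1e-9))
  if (ramp_frac == 0) shape <- rep(1, n)
  shape * total_deg * fs / sum(shape)
}

apply_turn_pause <- function(w, fs, total_deg) {
  n <- length(w)
  pause_len <- round(stats::runif(1, 0.3, 1.0) * fs)
  pause_len <- min(pause_len, max(1L, n - 2L * fs))
  c0 <- round(n / 2 - pause_len / 2)
  mask <- rep(1, n)
  mask[c0 + seq_len(pause_len)] <- 0
  # soften the mask edges over 0.15 s so velocity ramps to zero smoothly
  soft <- round(0.15 * fs)
  if (soft > 1) mask <- stats::filter(mask, rep(1 / soft, soft), sides = 2)
  mask[is.na(mask)] <- 1
  w <- w * as.numeric(mask)
  w * total_deg * fs / sum(w)            # renormalize to the full rotation
}

#' Generate one synthetic task recording
#'
#' Produces a recording composed of pre-task idle, the task template, and
#' post-task idle, plus idle sway and white sensor noise, together with the
#' exact ground-truth interval and a Tinetti-style label. Sit/stand
#' templates place `k` biphasic AP thrust pulses, `k` drawn from the
#' condition's attempt table (single-attempt dominant for normal subjects);
#' the stand-to-sit template is the time-reversed sit-to-stand template.
#' Turning templates ramp the vertical (yaw) angular velocity as a trapezoid
#' whose integral reaches exactly 360 degrees at the drawn average speed.
#'
#' @param task One of `"sit_to_stand"`, `"turn_360"`, `"stand_to_sit"`.
#' @param condition `"normal"` or `"deviating"`.
#' @param params A [synth_params()].
#' @param seed Integer seed; identical arguments give bitwise-identical
#'   recordings.
#' @param subject_id Subject identifier for the recording.
#' @return A list with elements `recording` (an `imu_recording`) and
#'   `label` (a `ground_truth_label` whose interval brackets the template).
#' @export
synth_recording <- function(task, condition = c("normal", "deviating"),
                            params = synth_params(), seed = 0L,
                            subject_id = "synthetic") {
  task <- match_task(task)
  condition <- match.arg(condition)
  validate_synth_params(params)
  with_local_seed(seed, {
    fs <- params$sampling_rate_hz
    pre_s <- runif_range(1, params$pre_idle_s)
    post_s <- runif_range(1, params$post_idle_s)
    turn_speed <- NULL
    if (task == "turn_360") {
      ts <- params$turn_speed[[condition]]
      turn_speed <- rtruncnorm(1, ts$mean, ts$sd, ts$min, ts$max)
      task_s <- 360 / turn_speed
    } else {
      task_s <- runif_range(1, params$task_duration_s)
    }
    n_pre <- round(pre_s * fs); n_task <- round(task_s * fs)
    n_post <- round(post_s * fs)
    n <- n_pre + n_task + n_post
    time_s <- (seq_len(n) - 1) / fs
    accel <- matrix(0, 3L, n); gyro <- matrix(0, 3L, n)

    # slow postural sway on every acceleration axis, present throughout
    for (ax in 1:3) {
      f <- stats::runif(1, 0.2, 0.4); phi <- stats::runif(1, 0, 2 * pi)
      amp <- params$idle_sway_amp * stats::runif(1, 0.5, 1)
      accel[ax, ] <- amp * sin(2 * pi * f * time_s + phi)
    }

    idx <- n_pre + seq_len(n_task)
    tt <- (seq_len(n_task) - 0.5) / fs   # local task time
    if (task == "turn_360") {
      w <- trapezoid_yaw(n_task, fs, 360, params$turn_ramp_frac)
      if (params$turn_pause && condition == "deviating") {
        w <- apply_turn_pause(w, fs, 360)
      }
      gyro[3L, idx] <- gyro[3L, idx] + w
      # stepping-related horizontal accelerations while turning
      for (ax in 1:2) {
        phi <- stats::runif(1, 0, 2 * pi)
        accel[ax, idx] <- accel[ax, idx] + 0.3 * sin(2 * pi * 1.5 * tt + phi)
      }
    } else {
      tab <- params$attempts[[task]][[condition]]
      k <- draw_attempt_count(tab)
      main_amp <- runif_range(1, params$ap_pulse_amp)
      ap <- ap_pulse_train(n_task, k, main_amp)
      vert_amp <- 0.8 * main_amp
      vert <- vert_amp * hann_lobe((seq_len(n_task) - 0.5) / n_task)
      pitch_amp <- stats::runif(1, 20, 40)
      pitch <- pitch_amp * sin(2 * pi * (seq_len(n_task) - 0.5) / n_task)
      if (task == "stand_to_sit") {
        ap <- rev(ap); vert <- -vert; pitch <- rev(pitch)
      }
      accel[1L, idx] <- accel[1L, idx] + ap
      accel[3L, idx] <- accel[3L, idx] + vert
      gyro[2L, idx] <- gyro[2L, idx] + pitch
    }

    if (params$noise_sd_accel > 0) {
      accel <- accel + matrix(stats::rnorm(3L * n, 0, params$noise_sd_accel), 3L)
    }
    if (params$noise_sd_gyro > 0) {
      gyro <- gyro + matrix(stats::rnorm(3L * n, 0, params$noise_sd_gyro), 3L)
    }

    rec <- imu_recording(subject_id, task, time_s, accel, gyro,
                         sampling_rate_hz = fs)
    truth <- motion_interval(time_s[n_pre + 1L], time_s[n_pre + n_task],
                             source = "ground_truth")
    full <- tinetti_full_mark(task)
    score <- if (condition == "normal") full else full - 1L
    label <- ground_truth_label(truth, task, score)
    list(recording = rec, label = label)
  })
}

#' Generate a synthetic cohort
#'
#' One recording per synthetic subject, with unique subject ids
#' (`S01`, `S02`, ...) and the requested class composition; the normal
#' subjects come first. Default class sizes mirror the reported cohorts
#' (45 normal : 14 deviating for sit-to-stand and stand-to-sit, 48 : 11 for
#' turning).
#'
#' @param task Balance task.
#' @param n_normal,n_deviating Class sizes; their sum must be positive.
#' @param params A [synth_params()].
#' @param seed Integer seed; per-subject seeds are derived from it.
#' @return A list of class `synth_cohort`: elements are
#'   `list(recording, label)` pairs, named by subject id.
#' @export
synth_cohort <- function(task, n_normal = 45L, n_deviating = 14L,
                         params = synth_params(), seed = 0L) {
  task <- match_task(task)
  n_normal <- as.integer(n_normal); n_deviating <- as.integer(n_deviating)
  if (n_normal < 0L || n_deviating < 0L) stop("class sizes must be >= 0")
  n <- n_normal + n_deviating
  if (n == 0L) stop("cohort must contain at least one subject")
  conditions <- rep(c("normal", "deviating"), c(n_normal, n_deviating))
  subj_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max, n))
  ids <- sprintf("S%02d", seq_len(n))
  cohort <- lapply(seq_len(n), function(i) {
    synth_recording(task, conditions[i], params, seed = subj_seeds[i],
                    subject_id = ids[i])
  })
  names(cohort) <- ids
  structure(cohort, class = "synth_cohort")
}

default_feature_dists <- function(task, params = synth_params()) {
  if (task == "turn_360") {
    list(normal = c(list(type = "truncnorm"), params$turn_speed$normal),
         deviating = c(list(type = "truncnorm"), params$turn_speed$deviating))
  } else {
    list(normal = list(type = "categorical",
                       probs = params$attempts[[task]]$normal),
         deviating = list(type = "categorical",
                          probs = params$attempts[[task]]$deviating))
  }
}

draw_feature_dist <- function(n, d, what) {
  if (is.null(d$type)) stop(what, ": distribution spec needs a 'type'")
  if (d$type == "categorical") {
    check_prob_table(d$probs, what)
    counts <- as.integer(names(d$probs))
    as.numeric(counts[sample.int(length(d$probs), n, replace = TRUE,
                                 prob = d$probs)])
  } else if (d$type == "truncnorm") {
    for (f in c("mean", "sd", "min", "max")) {
      if (is.null(d[[f]])) stop(what, ": truncnorm spec needs '", f, "'")
    }
    rtruncnorm(n, d$mean, d$sd, d$min, d$max)
  } else {
    stop(what, ": unknown distribution type '", d$type, "'")
  }
}

#' Draw feature-level synthetic cohorts
#'
#' Samples balance-feature values (AP peak counts for sit/stand tasks,
#' average turning speeds for turning) i.i.d. per condition, paired with
#' condition labels — the feature-space analogue of [synth_cohort()] used
#' to benchmark the classifiers without running the detector.
#'
#' @param task Balance task (selects the default distributions).
#' @param n_normal,n_deviating Class sizes.
#' @param dists Optional per-condition spec: a list with elements `normal`
#'   and `deviating`, each either
#'   `list(type = "categorical", probs = c("1" = ...))` or
#'   `list(type = "truncnorm", mean =, sd =, min =, max =)`. Defaults are
#'   the [synth_params()] calibration for the task.
#' @param seed Integer seed.
#' @return A list with `features` (numeric), `labels` (character,
#'   `"normal"`/`"deviating"`), and `subject_id`.
#' @export
synth_features <- function(task, n_normal = 45L, n_deviating = 14L,
                           dists = NULL, seed = 0L) {
  task <- match_task(task)
  n_normal <- as.integer(n_normal); n_deviating <- as.integer(n_deviating)
  if (n_normal < 0L || n_deviating < 0L) stop("class sizes must be >= 0")
  if (n_normal + n_deviating == 0L) stop("at least one subject required")
  if (is.null(dists)) dists <- default_feature_dists(task)
  if (!all(c("normal", "deviating") %in% names(dists))) {
    stop("dists must contain 'normal' and 'deviating' specs")
  }
  with_local_seed(seed, {
    f_norm <- draw_feature_dist(n_normal, dists$normal, "dists$normal")
    f_dev <- draw_feature_dist(n_deviating, dists$deviating, "dists$deviating")
    n <- n_normal + n_deviating
    list(features = c(f_norm, f_dev),
         labels = rep(c("normal", "deviating"), c(n_normal, n_deviating)),
         subject_id = sprintf("S%02d", seq_len(n)))
  })
}
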