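# Balance features: the anterior-posterior acceleration peak count for the
# sit/stand transitions and the average turning speed for the 360-degree
# turn.  A normal sit-to-stand shows a single AP thrust peak; repeated
# attempts to rise add peaks.  Slow turning is associated with deviation on
# the Tinetti turning items.

#' Count anterior-posterior acceleration peaks in an interval
#'
#' Counts local maxima of the detrended AP acceleration restricted to the
#' interval whose height reaches `frac` of the interval maximum (45 % by
#' default). Peaks are positive excursions: when the interval maximum is
#' not positive the count is 0. A 0.2 s minimum peak separation suppresses
#' noise-level jitter.
#'
#' @param accel_ap Detrended AP acceleration sequence (m/s^2), sample 1 at
#'   time 0.
#' @param interval A `motion_interval` within the signal.
#' @param sampling_rate_hz Sampling rate of `accel_ap`.
#' @param frac Relative height threshold (default 0.45).
#' @param min_sep_s Minimum peak separation in seconds (default 0.2).
#' @return Non-negative integer peak count.
#' @export
ap_peak_count <- function(accel_ap, interval, sampling_rate_hz = 40,
                          frac = 0.45, min_sep_s = 0.2) {
  stopifnot(inherits(interval, "motion_interval"))
  time_s <- (seq_along(accel_ap) - 1) / sampling_rate_hz
  idx <- interval_sample_idx(time_s, interval)
  if (length(idx) < 2L) stop("interval contains fewer than 2 samples")
  x <- accel_ap[idx]
  m <- max(x)
  if (m <= 0) return(0L)
  peaks <- find_local_maxima(x, min_height = frac * m,
                             min_sep = max(1L, round(min_sep_s * sampling_rate_hz)))
  length(peaks)
}

#' Average turning speed over an interval
#'
#' Net vertical-axis angular displacement across the interval divided by
#' the interval duration, in deg/s; the sign of the turn is discarded.
#'
#' @param ang_disp_vertical Cumulative vertical angular displacement
#'   (degrees), sample 1 at time 0.
#' @param interval A `motion_interval` with positive duration.
#' @param sampling_rate_hz Sampling rate of the displacement sequence.
#' @return Mean turning speed in deg/s (non-negative).
#' @export
mean_turn_speed <- function(ang_disp_vertical, interval,
                            sampling_rate_hz = 40) {
  stopifnot(inherits(interval, "motion_interval"))
  if (interval_duration(interval) <= 0) stop("interval duration must be positive")
  time_s <- (seq_along(ang_disp_vertical) - 1) / sampling_rate_hz
  idx <- interval_sample_idx(time_s, interval)
  if (length(idx) < 2L) stop("interval contains fewer than 2 samples")
  span <- time_s[idx[length(idx)]] - time_s[idx[1L]]
  abs(ang_disp_vertical[idx[length(idx)]] - ang_disp_vertical[idx[1L]]) / span
}

#' Extract the balance feature for a task
#'
#' Dispatches to [ap_peak_count()] for sit-to-stand and stand-to-sit, and
#' to [mean_turn_speed()] for turning 360 degrees.
#'
#' @param pre A `preprocessed_signals`.
#' @param interval The `motion_interval` to evaluate (detected or
#'   annotated).
#' @param task Balance task.
#' @param cfg A [pipeline_config()] (supplies the 45 % threshold and peak
#'   separation).
#' @return An object of class `feature_value` with fields `task`, `value`,
#'   and `interval_used`.
#' @export
extract_feature <- function(pre, interval, task, cfg = pipeline_config()) {
  stopifnot(inherits(pre, "preprocessed_signals"))
  task <- match_task(task)
  value <- if (task == "turn_360") {
    mean_turn_speed(pre$ang_disp[3L, ], interval, pre$sampling_rate_hz)
  } else {
    as.numeric(ap_peak_count(pre$accel_detrended[1L, ], interval,
                             pre$sampling_rate_hz, frac = cfg$ap_peak_frac,
                             min_sep_s = cfg$feature_peak_min_sep_s))
  }
  structure(list(task = task, value = value, interval_used = interval),
            class = "feature_value")
}

#' Per-subject feature table for a cohort
#'
#' Extracts the task feature for every subject, from the supplied detected
#' intervals or, when `intervals` is `NULL`, from the ground-truth
#' annotations.
#'
#' @param cohort A `synth_cohort` or named list of `list(recording, label)`.
#' @param intervals Optional named list of `motion_interval` (same subject
#'   ids as the cohort).
#' @param cfg A [pipeline_config()].
#' @return A data frame with columns `subject_id`, `task`, `feature`,
#'   `value`, `condition`, and `degenerate_flag`.
#' @export
cohort_features <- function(cohort, intervals = NULL, cfg = pipeline_config()) {
  ids <- names(cohort)
  rows <- lapply(ids, function(id) {
    item <- cohort[[id]]
    iv <- if (is.null(intervals)) item$label$interval else intervals[[id]]
    if (is.null(iv)) stop("no interval for subject ", id)
    pre <- preprocess_signals(item$recording)
    fv <- extract_feature(pre, iv, item$recording$task, cfg)
    data.frame(subject_id = id, task = fv$task,
               feature = if (fv$task == "turn_360") "mean_turn_speed"
                         else "ap_peak_count",
               value = fv$value, condition = item$label$condition,
               degenerate_flag = iv$degenerate_flag)
  })
  do.call(rbind, rows)
}
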