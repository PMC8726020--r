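# Rule-based postprocessing: the raw window-probability trace is smoothed
# with a mean filter, candidate intervals are anchored at nontask-probability
# peaks around the 0.5 task-probability crossings, and task-specific rules
# disambiguate when more than one candidate survives.

#' Find local maxima of a sequence
#'
#' A local maximum is a value strictly greater than both neighbors; a
#' plateau (run of equal values greater than the values on both sides)
#' contributes its midpoint. Maxima below `min_height` are discarded, and a
#' minimum separation is enforced by keeping higher peaks first (ties broken
#' by the earlier index). Endpoints of the sequence are never peaks.
#'
#' @param x Numeric sequence.
#' @param min_height Minimum peak height (default `-Inf`).
#' @param min_sep Minimum index separation between retained peaks
#'   (default 1).
#' @return Integer vector of peak indices, in increasing order.
#' @export
find_local_maxima <- function(x, min_height = -Inf, min_sep = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  runs <- rle(x)
  k <- length(runs$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  j <- 2:(k - 1L)
  is_peak <- runs$values[j] > runs$values[j - 1L] &
    runs$values[j] > runs$values[j + 1L]
  j <- j[is_peak]
  idx <- starts[j] + (runs$lengths[j] - 1L) %/% 2L
  idx <- idx[x[idx] >= min_height]
  if (length(idx) <= 1L || min_sep <= 1L) return(sort(idx))
  ord <- idx[order(-x[idx], idx)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

trace_step <- function(trace) {
  if (length(trace$center_times_s) < 2L) stop("trace too short")
  stats::median(diff(trace$center_times_s))
}

#' Smooth a probability trace with a mean filter
#'
#' Centered moving average of each probability channel; at the trace edges
#' the window is truncated and renormalized over the samples available.
#' Output probabilities are renormalized so the two channels sum to 1.
#'
#' @param trace A [probability_trace()].
#' @param mean_filter_s Filter length in seconds; 1, 1.25 and 1.5 s are the
#'   studied settings.
#' @return A smoothed [probability_trace()].
#' @export
smooth_trace <- function(trace, mean_filter_s = 1.0) {
  stopifnot(inherits(trace, "probability_trace"))
  step <- trace_step(trace)
  n_f <- as.integer(round(mean_filter_s / step))
  n <- length(trace$p_task)
  if (n_f < 1L) stop("mean_filter_s converts to fewer than 1 trace step")
  if (n_f > n) stop("mean filter longer than the trace")
  lo <- (n_f - 1L) %/% 2L; hi <- n_f %/% 2L
  running_mean <- function(x) {
    cs <- c(0, cumsum(x))
    i <- seq_len(n)
    a <- pmax(i - lo, 1L); b <- pmin(i + hi, n)
    (cs[b + 1L] - cs[a]) / (b - a + 1L)
  }
  pt <- running_mean(trace$p_task)
  pn <- running_mean(trace$p_nontask)
  tot <- pt + pn
  probability_trace(trace$center_times_s, pt / tot, pn / tot)
}

#' Identify candidate motion intervals from a smoothed trace
#'
#' For each maximal run where the task probability exceeds
#' `prob_threshold`, the interval start is the closest local maximum of the
#' nontask probability (height at least `peak_height`) before the upward
#' crossing, and the end is the first such maximum after the downward
#' crossing. When no qualifying peak exists on a side, the crossing time
#' itself is used and the interval is flagged degenerate. Intervals are
#' returned time-ordered and non-overlapping (a later start is clipped to
#' the previous end when the anchoring peaks would overlap).
#'
#' @param trace A smoothed [probability_trace()].
#' @param prob_threshold Task-probability crossing level (default 0.5).
#' @param peak_height Minimum nontask peak height (default 0.5).
#' @param min_sep_s Minimum separation between nontask peaks (default
#'   0.25 s).
#' @return An object of class `candidate_set`: a list with `intervals`
#'   (list of `motion_interval`) and `trace` (the trace used).
#' @export
candidate_intervals <- function(trace, prob_threshold = 0.5,
                                peak_height = 0.5, min_sep_s = 0.25) {
  stopifnot(inherits(trace, "probability_trace"))
  times <- trace$center_times_s
  n <- length(times)
  step <- trace_step(trace)
  min_sep <- max(1L, as.integer(round(min_sep_s / step)))
  peaks <- find_local_maxima(trace$p_nontask, min_height = peak_height,
                             min_sep = min_sep)
  above <- trace$p_task > prob_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  intervals <- list()
  prev_end <- -Inf
  for (j in runs) {
    s <- starts[j]; e <- ends[j]
    before <- peaks[peaks < s]
    after <- peaks[peaks > e]
    degenerate <- FALSE
    if (length(before)) start_t <- times[max(before)] else {
      start_t <- times[s]; degenerate <- TRUE
    }
    if (length(after)) end_t <- times[min(after)] else {
      end_t <- times[e]; degenerate <- TRUE
    }
    if (start_t < prev_end) start_t <- prev_end
    if (start_t >= end_t) next
    prev_end <- end_t
    intervals[[length(intervals) + 1L]] <-
      motion_interval(start_t, end_t, source = "detected",
                      degenerate_flag = degenerate)
  }
  structure(list(intervals = intervals, trace = trace),
            class = "candidate_set")
}

interval_sample_idx <- function(time_s, interval) {
  which(time_s >= interval$start_s - 1e-9 & time_s <= interval$end_s + 1e-9)
}

#' Select the final motion interval among candidates
#'
#' With a single candidate, returns it unchanged. With several, applies the
#' task rule: sit-to-stand and stand-to-sit keep the candidate with the
#' greatest anterior-posterior acceleration range; turning keeps, among
#' candidates whose cumulative vertical rotation from their start stays
#' below `turn_limit_deg` (plus a `turn_tolerance_frac` slack for
#' integration error), the one with the greatest rotation — if none is
#' admissible, the candidate with the smallest rotation is returned flagged
#' degenerate. With no candidate at all, the whole recording is returned
#' flagged degenerate, so downstream assessment always has an interval.
#'
#' @param candidates A `candidate_set` from [candidate_intervals()].
#' @param pre The `preprocessed_signals` of the same recording.
#' @param task Balance task of the recording.
#' @param cfg A [pipeline_config()] (supplies the turning limit and slack).
#' @return A single `motion_interval`.
#' @export
select_interval <- function(candidates, pre, task, cfg = pipeline_config()) {
  stopifnot(inherits(candidates, "candidate_set"),
            inherits(pre, "preprocessed_signals"))
  task <- match_task(task)
  ivs <- candidates$intervals
  if (!length(ivs)) {
    n <- length(pre$time_s)
    return(motion_interval(pre$time_s[1L], pre$time_s[n],
                           source = "detected", degenerate_flag = TRUE))
  }
  ivs <- ivs[order(vapply(ivs, `[[`, 0, "start_s"))]
  if (length(ivs) == 1L) return(ivs[[1L]])
  if (task == "turn_360") {
    movement <- vapply(ivs, function(iv) {
      idx <- interval_sample_idx(pre$time_s, iv)
      if (length(idx) < 2L) return(0)
      abs(pre$ang_disp[3L, idx[length(idx)]] - pre$ang_disp[3L, idx[1L]])
    }, 0)
    limit <- cfg$turn_limit_deg * (1 + cfg$turn_tolerance_frac)
    admissible <- which(movement <= limit)
    if (length(admissible)) {
      ivs[[admissible[which.max(movement[admissible])]]]
    } else {
      iv <- ivs[[which.min(movement)]]
      iv$degenerate_flag <- TRUE
      iv
    }
  } else {
    ap_range <- vapply(ivs, function(iv) {
      idx <- interval_sample_idx(pre$time_s, iv)
      if (!length(idx)) return(-Inf)
      diff(range(pre$accel_detrended[1L, idx]))
    }, 0)
    ivs[[which.max(ap_range)]]
  }
}

#' Detect the motion interval of a recording
#'
#' Full detection composition: preprocess, predict the window-probability
#' trace, smooth it with the configured mean filter, extract candidate
#' intervals, and apply the task-specific selection rule. Deterministic
#' given the detector and configuration.
#'
#' @param rec An `imu_recording`.
#' @param detector A trained `conv_lstm_detector` for `rec$task`.
#' @param cfg A [pipeline_config()].
#' @return A `motion_interval` with source `"detected"`.
#' @export
detect_motion <- function(rec, detector, cfg = pipeline_config()) {
  pre <- preprocess_signals(rec)
  trace <- predict_trace(detector, pre, window_s = cfg$window_s,
                         step_s = cfg$step_s)
  smoothed <- smooth_trace(trace, cfg$mean_filter_s)
  cands <- candidate_intervals(smoothed, prob_threshold = cfg$prob_threshold,
                               peak_height = cfg$peak_height_threshold,
                               min_sep_s = cfg$peak_min_sep_s)
  select_interval(cands, pre, rec$task, cfg)
}

#' Postprocess an existing probability trace into a motion interval
#'
#' Like [detect_motion()] but starting from an already-computed trace —
#' convenient when traces come from a leave-one-subject-out harness.
#'
#' @param trace A raw [probability_trace()].
#' @param pre The recording's `preprocessed_signals`.
#' @param task Balance task.
#' @param cfg A [pipeline_config()].
#' @return A `motion_interval`.
#' @export
postprocess_trace <- function(trace, pre, task, cfg = pipeline_config()) {
  smoothed <- smooth_trace(trace, cfg$mean_filter_s)
  cands <- candidate_intervals(smoothed, prob_threshold = cfg$prob_threshold,
                               peak_height = cfg$peak_height_threshold,
                               min_sep_s = cfg$peak_min_sep_s)
  select_interval(cands, pre, task, cfg)
}
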