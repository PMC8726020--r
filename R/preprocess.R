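#' Detrend the accelerometer channels
#'
#' Subtracts the per-axis mean from each acceleration channel, removing the
#' gravity component and any constant sensor bias.
#'
#' @param rec An `imu_recording`.
#' @return A 3 x T matrix of zero-mean accelerations (m/s^2).
#' @export
detrend_accel <- function(rec) {
  validate_recording(rec)
  rec$accel - rowMeans(rec$accel)
}

#' Integrate the gyroscope into angular displacement
#'
#' Cumulative rectangle-rule integration (step `1/sampling_rate_hz`) of each
#' angular-velocity channel, anchored at 0 degrees at the first sample.
#' Gyroscope drift is not corrected: at the sensor's specified 0.05 deg/s
#' drift rate and task durations under 30 s it is negligible.
#'
#' @param rec An `imu_recording`.
#' @return A 3 x T matrix of cumulative angular displacement (degrees);
#'   column 1 is all zeros.
#' @export
integrate_gyro <- function(rec) {
  validate_recording(rec)
  dt <- 1 / rec$sampling_rate_hz
  t(apply(rec$gyro, 1L, function(w) {
    c(0, cumsum(w[-length(w)])) * dt
  }))
}

#' Preprocess a recording for the detector
#'
#' Bundles [detrend_accel()] and [integrate_gyro()] into the six-channel
#' signal matrix the motion detector consumes.
#'
#' @param rec An `imu_recording`.
#' @return An object of class `preprocessed_signals` with fields
#'   `accel_detrended` (3 x T), `ang_disp` (3 x T), `time_s`, and
#'   `sampling_rate_hz`.
#' @export
preprocess_signals <- function(rec) {
  structure(list(accel_detrended = detrend_accel(rec),
                 ang_disp = integrate_gyro(rec),
                 time_s = rec$time_s,
                 sampling_rate_hz = rec$sampling_rate_hz),
            class = "preprocessed_signals")
}

#' Segment preprocessed signals into soft-labeled sliding windows
#'
#' Slides a `window_s`-long window over the six preprocessed channels in
#' steps of `step_s`. When a ground-truth interval is given, each window
#' receives a soft label: the fraction of the window's continuous time span
#' that overlaps the interval is the task probability, the remainder the
#' nontask probability (e.g. a 0.75 s window covering 0.5 s of task carries
#' the label (0.67, 0.33)). Windows that would extend past the end of the
#' recording are dropped, keeping the detector input shape fixed.
#'
#' @param pre A `preprocessed_signals`.
#' @param truth Optional `motion_interval` ground truth; when `NULL`
#'   (inference) no labels are attached.
#' @param window_s Window length in seconds (default 0.75).
#' @param step_s Window stride in seconds (default 0.025).
#' @return An object of class `window_set`: a list with the window tensor
#'   `x` (N x W x 6, channels: detrended AP/ML/vertical acceleration then
#'   AP/ML/vertical angular displacement), `center_time_s`, `start_time_s`,
#'   and `soft_labels` (N x 2 matrix of (p_task, p_nontask), or `NULL`).
#' @export
make_windows <- function(pre, truth = NULL, window_s = 0.75, step_s = 0.025) {
  stopifnot(inherits(pre, "preprocessed_signals"))
  fs <- pre$sampling_rate_hz
  n <- length(pre$time_s)
  w <- as.integer(round(window_s * fs))
  step <- max(1L, as.integer(round(step_s * fs)))
  if (w < 1L) stop("window_s converts to fewer than 1 sample")
  if (w > n) stop("window (", w, " samples) longer than recording (", n, " samples)")
  starts <- seq.int(1L, n - w + 1L, by = step)
  nw <- length(starts)
  channels <- rbind(pre$accel_detrended, pre$ang_disp)  # 6 x T
  x <- array(0, dim = c(nw, w, 6L))
  for (j in seq_len(w)) {
    x[, j, ] <- t(channels[, starts + (j - 1L), drop = FALSE])
  }
  start_time <- pre$time_s[starts]
  center_time <- start_time + window_s / 2
  soft <- NULL
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "motion_interval"))
    lo <- pmax(start_time, truth$start_s)
    hi <- pmin(start_time + window_s, truth$end_s)
    p_task <- pmin(1, pmax(0, (hi - lo) / window_s))
    soft <- cbind(p_task = p_task, p_nontask = 1 - p_task)
  }
  structure(list(x = x, center_time_s = center_time,
                 start_time_s = start_time, window_s = window_s,
                 step_s = step_s, sampling_rate_hz = fs,
                 soft_labels = soft),
            class = "window_set")
}

#' Extract one window segment
#'
#' Convenience accessor returning the `i`-th window of a [make_windows()]
#' result as a standalone segment.
#'
#' @param ws A `window_set`.
#' @param i Window index.
#' @return A list with `samples` (W x 6 matrix), `center_time_s`, and
#'   `soft_label` (length-2 vector or `NULL`).
#' @export
window_segment <- function(ws, i) {
  stopifnot(inherits(ws, "window_set"))
  i <- as.integer(i)
  if (i < 1L || i > n_windows(ws)) stop("window index out of range")
  list(samples = ws$x[i, , ],
       center_time_s = ws$center_time_s[i],
       soft_label = if (is.null(ws$soft_labels)) NULL else ws$soft_labels[i, ])
}

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$x)[1L]
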