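#' @keywords internal
"_PACKAGE"

# Canonical task names and axis order used throughout the package.
# Axis order is AP (anterior-posterior), ML (medio-lateral), vertical;
# the vertical axis is the turning (yaw) axis.
BALANCE_TASKS <- c("sit_to_stand", "turn_360", "stand_to_sit")
AXIS_NAMES <- c("ap", "ml", "v")
RECORDING_COLUMNS <- c("time_s", "acc_ap", "acc_ml", "acc_v",
                       "gyr_ap", "gyr_ml", "gyr_v")

#' Full Tinetti POMA-B mark for a balance task
#'
#' Sit-to-stand is graded out of 4 (arises from the chair 0-2, attempts to
#' arise 0-2); turning 360 degrees and stand-to-sit are graded out of 2.
#' A subject is considered normal on a task exactly when they receive the
#' full mark; anything less is "deviating from healthy".
#'
#' @param task One of `"sit_to_stand"`, `"turn_360"`, `"stand_to_sit"`.
#' @return Integer full mark (4 or 2).
#' @export
tinetti_full_mark <- function(task) {
  task <- match_task(task)
  if (task == "sit_to_stand") 4L else 2L
}

match_task <- function(task) {
  if (!is.character(task) || length(task) != 1L || !(task %in% BALANCE_TASKS)) {
    stop("unknown task: ", paste(task, collapse = ", "),
         " (expected one of ", paste(BALANCE_TASKS, collapse = ", "), ")")
  }
  task
}

#' Construct an IMU recording
#'
#' A single subject's six-channel inertial time series for one known balance
#' task, sampled at the lumbar (L4) sensor. Accelerations are in m/s^2 and
#' angular velocities in deg/s, both in AP / ML / vertical axis order.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param task One of `"sit_to_stand"`, `"turn_360"`, `"stand_to_sit"`.
#' @param time_s Monotonically increasing sample times in seconds.
#' @param accel 3 x T matrix of accelerations (rows: AP, ML, vertical).
#' @param gyro 3 x T matrix of angular velocities (same row order).
#' @param sampling_rate_hz Sampling rate in Hz (default 40).
#' @param axis_map Optional named character vector mapping canonical column
#'   names to the column names of the source file (kept for provenance).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(subject_id, task, time_s, accel, gyro,
                          sampling_rate_hz = 40, axis_map = NULL) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         task = match_task(task),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         time_s = as.numeric(time_s),
         accel = as.matrix(accel),
         gyro = as.matrix(gyro),
         axis_map = axis_map),
    class = "imu_recording")
  rownames(rec$accel) <- AXIS_NAMES
  rownames(rec$gyro) <- AXIS_NAMES
  validate_recording(rec)
}

#' Validate an IMU recording
#'
#' Checks the structural invariants: equal channel lengths, a positive
#' sampling rate, and a uniform time step within 1 % of `1/sampling_rate_hz`.
#'
#' @param rec An `imu_recording`.
#' @return The recording, invisibly unchanged, or an error.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "imu_recording")) stop("not an imu_recording")
  n <- length(rec$time_s)
  if (n < 2L) stop("recording must contain at least 2 samples")
  if (!is.finite(rec$sampling_rate_hz) || rec$sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive number")
  }
  if (nrow(rec$accel) != 3L || nrow(rec$gyro) != 3L) {
    stop("accel and gyro must have 3 rows (AP, ML, vertical)")
  }
  if (ncol(rec$accel) != n || ncol(rec$gyro) != n) {
    stop("channel lengths differ from length of time_s")
  }
  if (anyNA(rec$accel) || anyNA(rec$gyro) || anyNA(rec$time_s)) {
    stop("recording contains missing values")
  }
  dt <- diff(rec$time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  expected <- 1 / rec$sampling_rate_hz
  if (any(abs(dt - expected) > 0.01 * expected)) {
    stop("time step deviates more than 1% from 1/sampling_rate_hz")
  }
  rec
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s, task %s: %d samples at %g Hz (%.2f s)\n",
              x$subject_id, x$task, length(x$time_s), x$sampling_rate_hz,
              recording_duration(x)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `imu_recording`.
#' @return Time of the last sample, in seconds from recording start.
#' @export
recording_duration <- function(rec) {
  rec$time_s[length(rec$time_s)]
}

#' Construct a motion interval
#'
#' A closed time interval `[start_s, end_s]` locating a task motion inside a
#' recording, either annotated (ground truth / manual) or produced by the
#' detector.
#'
#' @param start_s,end_s Interval bounds in seconds, `0 <= start_s < end_s`.
#' @param source One of `"ground_truth"`, `"manual"`, `"detected"`.
#' @param degenerate_flag `TRUE` when fallback rules (no usable probability
#'   peak, or no candidate at all) produced the interval.
#' @return An object of class `motion_interval`.
#' @export
motion_interval <- function(start_s, end_s,
                            source = c("ground_truth", "manual", "detected"),
                            degenerate_flag = FALSE) {
  source <- match.arg(source)
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  if (!is.finite(start_s) || !is.finite(end_s)) stop("interval bounds must be finite")
  if (start_s < 0) stop("start_s must be >= 0")
  if (start_s >= end_s) stop("interval must satisfy start_s < end_s")
  structure(list(start_s = start_s, end_s = end_s, source = source,
                 degenerate_flag = isTRUE(degenerate_flag)),
            class = "motion_interval")
}

#' @export
print.motion_interval <- function(x, ...) {
  cat(sprintf("<motion_interval> [%.3f, %.3f] s (%s%s)\n", x$start_s, x$end_s,
              x$source, if (x$degenerate_flag) ", degenerate" else ""))
  invisible(x)
}

interval_duration <- function(interval) interval$end_s - interval$start_s

#' Construct a ground-truth label
#'
#' Couples the annotated motion interval with the Tinetti POMA-B subscore
#' for the task. The condition is derived from the subscore: a subject is
#' `"normal"` exactly when the subscore equals the full mark for the task
#' (4 for sit-to-stand, 2 for turning and stand-to-sit), otherwise
#' `"deviating"`.
#'
#' @param interval A `motion_interval`.
#' @param task The balance task the subscore refers to.
#' @param tinetti_subscore Non-negative integer subscore.
#' @param condition Optional; if supplied it must agree with the subscore.
#' @return An object of class `ground_truth_label`.
#' @export
ground_truth_label <- function(interval, task, tinetti_subscore,
                               condition = NULL) {
  task <- match_task(task)
  if (!inherits(interval, "motion_interval")) stop("interval must be a motion_interval")
  sc <- as.integer(tinetti_subscore)
  full <- tinetti_full_mark(task)
  if (is.na(sc) || sc < 0L) stop("tinetti_subscore must be a non-negative integer")
  if (sc > full) stop("tinetti_subscore exceeds the full mark (", full, ") for ", task)
  derived <- if (sc == full) "normal" else "deviating"
  if (!is.null(condition)) {
    condition <- match.arg(condition, c("normal", "deviating"))
    if (condition != derived) {
      stop("condition '", condition, "' inconsistent with tinetti_subscore ",
           sc, " for task ", task)
    }
  }
  structure(list(interval = interval, task = task,
                 condition = derived, tinetti_subscore = sc),
            class = "ground_truth_label")
}

# ---------------------------------------------------------------------------
# Recording CSV I/O.  Canonical header:
#   time_s,acc_ap,acc_ml,acc_v,gyr_ap,gyr_ml,gyr_v

#' Read an IMU recording from CSV
#'
#' The file must contain a header naming the time column and the six sensor
#' channels. Columns can be renamed through `axis_map`, a named character
#' vector from canonical names (`time_s`, `acc_ap`, ..., `gyr_v`) to the
#' file's column names. Units are assumed m/s^2 and deg/s; recordings from
#' devices reporting g can be rescaled with `scale_accel`.
#'
#' @param path CSV file path.
#' @param subject_id,task Recording metadata (defaults parsed from the file
#'   name are deliberately not attempted; pass them explicitly).
#' @param axis_map Optional canonical-to-file column name mapping.
#' @param sampling_rate_hz Sampling rate; if `NULL`, inferred from the
#'   median time step.
#' @param scale_accel,scale_gyro Multiplicative unit conversions applied on
#'   read (e.g. 9.80665 for accelerations stored in g).
#' @return An `imu_recording`.
#' @export
read_recording <- function(path, subject_id = "subject", task = "sit_to_stand",
                           axis_map = NULL, sampling_rate_hz = NULL,
                           scale_accel = 1, scale_gyro = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (nrow(df) == 0L) stop("empty recording file: ", path)
  cols <- RECORDING_COLUMNS
  file_cols <- cols
  if (!is.null(axis_map)) {
    idx <- match(names(axis_map), cols)
    if (anyNA(idx)) stop("axis_map names must be canonical column names")
    file_cols[idx] <- unname(axis_map)
  }
  missing <- setdiff(file_cols, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  dat <- df[, file_cols]
  names(dat) <- cols
  time_s <- dat$time_s
  if (any(diff(time_s) <= 0)) stop("time column is not strictly increasing")
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- 1 / stats::median(diff(time_s))
  }
  imu_recording(
    subject_id = subject_id, task = task, time_s = time_s,
    accel = t(as.matrix(dat[, c("acc_ap", "acc_ml", "acc_v")])) * scale_accel,
    gyro = t(as.matrix(dat[, c("gyr_ap", "gyr_ml", "gyr_v")])) * scale_gyro,
    sampling_rate_hz = sampling_rate_hz, axis_map = axis_map)
}

#' Write an IMU recording to CSV
#'
#' Writes the canonical column order
#' `time_s,acc_ap,acc_ml,acc_v,gyr_ap,gyr_ml,gyr_v`.
#'
#' @param rec An `imu_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  df <- data.frame(time_s = rec$time_s,
                   acc_ap = rec$accel[1, ], acc_ml = rec$accel[2, ],
                   acc_v = rec$accel[3, ],
                   gyr_ap = rec$gyro[1, ], gyr_ml = rec$gyro[2, ],
                   gyr_v = rec$gyro[3, ])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Annotation JSON I/O.  A JSON array of objects
#   {subject_id, task, start_s, end_s, tinetti_subscore, [source],
#    [degenerate_flag]}

#' Read interval annotations
#'
#' @param path JSON file: an array of objects with fields `subject_id`,
#'   `task`, `start_s`, `end_s`, `tinetti_subscore` and optionally `source`
#'   and `degenerate_flag`.
#' @return A named list of `ground_truth_label`, keyed by subject id.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw)) stop("annotation file must contain a JSON array")
  labels <- lapply(raw, function(item) {
    for (f in c("subject_id", "task", "start_s", "end_s", "tinetti_subscore")) {
      if (is.null(item[[f]])) stop("annotation missing field '", f, "'")
    }
    iv <- motion_interval(item$start_s, item$end_s,
                          source = item$source %||% "ground_truth",
                          degenerate_flag = isTRUE(item$degenerate_flag))
    ground_truth_label(iv, item$task, item$tinetti_subscore,
                       condition = item$condition)
  })
  names(labels) <- vapply(raw, function(item) as.character(item$subject_id), "")
  if (anyDuplicated(names(labels))) stop("duplicate subject_id in annotations")
  labels
}

#' Write interval annotations
#'
#' Inverse of [read_annotations()].
#'
#' @param labels Named list of `ground_truth_label` (names are subject ids).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(labels, path) {
  items <- lapply(seq_along(labels), function(i) {
    lb <- labels[[i]]
    list(subject_id = names(labels)[i], task = lb$task,
         start_s = lb$interval$start_s, end_s = lb$interval$end_s,
         source = lb$interval$source,
         degenerate_flag = lb$interval$degenerate_flag,
         condition = lb$condition, tinetti_subscore = lb$tinetti_subscore)
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
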