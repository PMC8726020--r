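# End-to-end synthetic benchmarks: the detection benchmark runs the full
# pipeline (conv-LSTM + mean filter + interval rules) under
# leave-one-subject-out evaluation on a seeded synthetic cohort; the
# classification benchmark evaluates a classifier on feature-level cohorts
# over repeated draws.

#' Leave-one-subject-out detection benchmark on a synthetic cohort
#'
#' Generates a seeded cohort for the task, trains a detector per LOSO fold,
#' postprocesses each held-out probability trace into a motion interval,
#' and scores per-sample detection accuracy against the ground truth.
#'
#' @param task Balance task.
#' @param n_normal,n_deviating Cohort composition (defaults 9 and 3).
#' @param params A [synth_params()].
#' @param cfg A [pipeline_config()]; `cfg$detector` controls the detector
#'   and `cfg$seed` seeds both cohort generation and training.
#' @return A list with `mean_accuracy`, a `per_subject` data frame
#'   (accuracy, detected bounds, degenerate flag, condition), the detected
#'   `intervals`, and the `cohort`.
#' @export
detection_benchmark <- function(task, n_normal = 9L, n_deviating = 3L,
                                params = synth_params(),
                                cfg = pipeline_config()) {
  task <- match_task(task)
  cohort <- synth_cohort(task, n_normal, n_deviating, params, seed = cfg$seed)
  det_cfg <- cfg$detector
  det_cfg$seed <- cfg$seed
  loso <- loso_train_predict(cohort, det_cfg, window_s = cfg$window_s,
                             step_s = cfg$step_s)
  ids <- names(cohort)
  intervals <- vector("list", length(ids)); names(intervals) <- ids
  rows <- lapply(ids, function(id) {
    item <- cohort[[id]]
    pre <- preprocess_signals(item$recording)
    iv <- postprocess_trace(loso$traces[[id]], pre, task, cfg)
    intervals[[id]] <<- iv
    acc <- detection_accuracy(iv, item$label$interval,
                              recording_duration(item$recording),
                              item$recording$sampling_rate_hz)
    data.frame(subject_id = id, condition = item$label$condition,
               accuracy = acc, start_s = iv$start_s, end_s = iv$end_s,
               truth_start_s = item$label$interval$start_s,
               truth_end_s = item$label$interval$end_s,
               degenerate_flag = iv$degenerate_flag)
  })
  per_subject <- do.call(rbind, rows)
  list(mean_accuracy = mean(per_subject$accuracy),
       per_subject = per_subject, intervals = intervals, cohort = cohort)
}

#' Repeated feature-level classification benchmark
#'
#' Draws `n_reps` feature cohorts with [synth_features()] (seeds
#' `seed, seed + 1, ...`), evaluates the classifier under
#' leave-one-subject-out cross-validation on each, and averages the pooled
#' accuracy over repetitions.
#'
#' @param task Balance task (selects default feature distributions).
#' @param spec A [classifier_spec()].
#' @param dists Optional distribution spec passed to [synth_features()].
#' @param n_normal,n_deviating Class sizes (defaults 45 and 14).
#' @param n_reps Number of Monte-Carlo repetitions (default 50).
#' @param seed Base seed.
#' @return A list with `mean_accuracy`, `mean_auc`, and a `per_rep` data
#'   frame.
#' @export
classification_benchmark <- function(task, spec = classifier_spec("knn"),
                                     dists = NULL, n_normal = 45L,
                                     n_deviating = 14L, n_reps = 50L,
                                     seed = 0L) {
  rows <- lapply(seq_len(n_reps), function(r) {
    draw <- synth_features(task, n_normal, n_deviating, dists,
                           seed = seed + r - 1L)
    res <- loso_assess(draw$features, draw$labels, spec, draw$subject_id)
    data.frame(rep = r, seed = seed + r - 1L,
               accuracy = res$accuracy, auc = res$auc)
  })
  per_rep <- do.call(rbind, rows)
  list(mean_accuracy = mean(per_rep$accuracy), mean_auc = mean(per_rep$auc),
       per_rep = per_rep)
}
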