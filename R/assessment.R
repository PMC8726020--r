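# Normal vs deviating-from-healthy classification on the single balance
# feature, leave-one-subject-out evaluation, ROC/AUC, and McNemar agreement
# between manual and detected labels.  The positive class throughout is
# "deviating".

#' Classifier specification
#'
#' @param kind `"one_class_svm"` (trained on the normal class only,
#'   radial kernel), `"lda"`, or `"knn"`.
#' @param knn_k Number of neighbors for k-NN; must be odd (default 5).
#' @param ocsvm_nu One-class SVM nu parameter in (0, 1) (default 0.1).
#' @param ocsvm_gamma Radial-kernel width; default `NULL` uses 1 over the
#'   feature dimension.
#' @param standardize Standardize features with training-fold statistics
#'   before fitting (default `TRUE`).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("knn", "one_class_svm", "lda"),
                            knn_k = 5L, ocsvm_nu = 0.1, ocsvm_gamma = NULL,
                            standardize = TRUE) {
  kind <- match.arg(kind)
  knn_k <- as.integer(knn_k)
  if (knn_k < 1L || knn_k %% 2L == 0L) stop("knn_k must be odd and positive")
  if (ocsvm_nu <= 0 || ocsvm_nu >= 1) stop("ocsvm_nu must lie in (0, 1)")
  structure(list(kind = kind, knn_k = knn_k, ocsvm_nu = ocsvm_nu,
                 ocsvm_gamma = ocsvm_gamma, standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

check_labels <- function(labels) {
  if (!all(labels %in% c("normal", "deviating"))) {
    stop("labels must be 'normal' or 'deviating'")
  }
  labels
}

#' Fit a classifier on training features and predict a test feature
#'
#' The one-class SVM trains on the normal-class features only and flags
#' out-of-distribution values as deviating; LDA and k-NN train on both
#' classes. Scores are oriented so that larger means more deviating:
#' the negated decision function for the one-class SVM, the posterior
#' probability of the deviating class for LDA, and the fraction of
#' deviating neighbors for k-NN. k-NN casts exactly k votes; training
#' points tied at the k-th smallest distance share the remaining weight
#' equally (the expectation of random tie-breaking), so the vote does not
#' depend on the ordering of equidistant subjects, and an exactly split
#' vote is called deviating (favoring sensitivity in a screening setting).
#'
#' @param spec A [classifier_spec()].
#' @param train_features Numeric vector of training feature values.
#' @param train_labels Character vector (`"normal"`/`"deviating"`).
#' @param test_feature Numeric vector of feature values to classify.
#' @return A list with `label` (character vector) and `score` (numeric
#'   vector, larger = more deviating).
#' @export
fit_predict <- function(spec, train_features, train_labels, test_feature) {
  stopifnot(inherits(spec, "classifier_spec"))
  train_labels <- check_labels(train_labels)
  if (length(train_features) != length(train_labels)) {
    stop("train_features and train_labels differ in length")
  }
  switch(spec$kind,
         knn = fit_predict_knn(spec, train_features, train_labels, test_feature),
         lda = fit_predict_lda(spec, train_features, train_labels, test_feature),
         one_class_svm = fit_predict_ocsvm(spec, train_features, train_labels,
                                           test_feature))
}

standardizer <- function(x, enabled) {
  mu <- if (enabled) mean(x) else 0
  sd_ <- if (enabled) max(stats::sd(x), 1e-8) else 1
  function(z) (z - mu) / sd_
}

fit_predict_knn <- function(spec, train_features, train_labels, test_feature) {
  if (length(unique(train_labels)) < 2L) {
    stop("k-NN requires both classes in the training set")
  }
  k <- min(spec$knn_k, length(train_features))
  std <- standardizer(train_features, spec$standardize)
  tr <- std(train_features); te <- std(test_feature)
  score <- vapply(te, function(z) {
    d <- abs(tr - z)
    # exactly k votes; training points tied at the k-th distance share the
    # remaining weight equally, so the vote does not depend on the ordering
    # of equidistant subjects
    dk <- sort(d, partial = k)[k]
    eps <- 1e-9 * (1 + dk)
    closer <- d < dk - eps
    tied <- abs(d - dk) <= eps
    w_tie <- (k - sum(closer)) / sum(tied)
    (sum(train_labels[closer] == "deviating") +
       w_tie * sum(train_labels[tied] == "deviating")) / k
  }, 0)
  list(label = ifelse(score >= 0.5, "deviating", "normal"), score = score)
}

fit_predict_lda <- function(spec, train_features, train_labels, test_feature) {
  if (length(unique(train_labels)) < 2L) {
    stop("LDA requires both classes in the training set")
  }
  std <- standardizer(train_features, spec$standardize)
  fit <- MASS::lda(x = matrix(std(train_features), ncol = 1L),
                   grouping = factor(train_labels,
                                     levels = c("normal", "deviating")))
  pr <- stats::predict(fit, matrix(std(test_feature), ncol = 1L))
  score <- pr$posterior[, "deviating"]
  list(label = as.character(pr$class), score = unname(score))
}

fit_predict_ocsvm <- function(spec, train_features, train_labels, test_feature) {
  normals <- train_features[train_labels == "normal"]
  if (!length(normals)) {
    stop("one-class SVM requires normal-class training samples")
  }
  std <- standardizer(normals, spec$standardize)
  gamma <- spec$ocsvm_gamma %||% 1
  fit <- e1071::svm(x = matrix(std(normals), ncol = 1L),
                    type = "one-classification", kernel = "radial",
                    nu = spec$ocsvm_nu, gamma = gamma, scale = FALSE)
  pr <- stats::predict(fit, matrix(std(test_feature), ncol = 1L),
                       decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  # points on the decision boundary count as inliers: with duplicate-heavy
  # count features the bulk of the normal class can sit exactly on the
  # margin, where the raw sign of the decision value is numerical noise
  list(label = ifelse(dv >= -1e-6, "normal", "deviating"), score = -dv)
}

#' Leave-one-subject-out assessment of a classifier
#'
#' Holds out each subject in turn, fits the classifier on the remaining
#' subjects' features, and predicts the held-out subject. Accuracy,
#' AUC and the confusion counts (positive class: deviating) are pooled
#' over the held-out predictions.
#'
#' @param features Numeric vector of per-subject feature values.
#' @param labels Character vector of conditions (`"normal"`/`"deviating"`).
#' @param spec A [classifier_spec()].
#' @param subject_id Optional subject ids (defaults to `S01`, `S02`, ...).
#' @return An object of class `eval_result`: accuracy, auc, confusion
#'   counts `tp`/`tn`/`fp`/`fn`, and a per-subject `predictions` data frame
#'   with held-out labels and scores.
#' @export
loso_assess <- function(features, labels, spec = classifier_spec("knn"),
                        subject_id = NULL) {
  labels <- check_labels(labels)
  n <- length(features)
  if (n < 2L) stop("LOSO requires at least 2 subjects")
  if (length(labels) != n) stop("features and labels differ in length")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (is.null(subject_id)) subject_id <- sprintf("S%02d", seq_len(n))
  pred <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    out <- fit_predict(spec, features[-i], labels[-i], features[i])
    pred[i] <- out$label; score[i] <- out$score
  }
  tp <- sum(pred == "deviating" & labels == "deviating")
  tn <- sum(pred == "normal" & labels == "normal")
  fp <- sum(pred == "deviating" & labels == "normal")
  fn <- sum(pred == "normal" & labels == "deviating")
  structure(list(accuracy = (tp + tn) / n,
                 auc = roc_auc(score, labels),
                 tp = tp, tn = tn, fp = fp, fn = fn,
                 predictions = data.frame(subject_id = subject_id,
                                          truth = labels, pred = pred,
                                          score = score)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> accuracy %.3f, AUC %.3f (TP %d, TN %d, FP %d, FN %d)\n",
              x$accuracy, x$auc, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Per-sample detection accuracy of an interval against the truth
#'
#' Binary agreement between the detected-interval indicator and the
#' ground-truth indicator, evaluated on the recording's sample grid — the
#' fraction of samples on which the two intervals agree about task
#' membership, counting true task and true nontask samples alike.
#'
#' @param detected,truth `motion_interval` objects within the recording.
#' @param duration_s Recording duration in seconds.
#' @param sampling_rate_hz Sample rate of the grid (default 40).
#' @return Agreement fraction in \[0, 1\].
#' @export
detection_accuracy <- function(detected, truth, duration_s,
                               sampling_rate_hz = 40) {
  stopifnot(inherits(detected, "motion_interval"),
            inherits(truth, "motion_interval"))
  n <- round(duration_s * sampling_rate_hz)
  t <- (seq_len(n) - 1) / sampling_rate_hz
  ind <- function(iv) t >= iv$start_s - 1e-9 & t <= iv$end_s + 1e-9
  mean(ind(detected) == ind(truth))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the empirical ROC, computed in its
#' rank-statistic (Mann-Whitney) form; tied scores are handled by rank
#' averaging. Scores must be oriented so larger means more deviating.
#'
#' @param scores Numeric decision scores.
#' @param labels Character conditions (`"normal"`/`"deviating"`); both
#'   classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_labels(labels)
  pos <- labels == "deviating"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' McNemar agreement test on discordant counts
#'
#' Test statistic `z^2 = (n12 - n21)^2 / (n12 + n21)` referred to the
#' chi-square distribution with 1 degree of freedom; `n12` counts subjects
#' the first procedure classifies positive and the second negative, `n21`
#' the reverse. With no discordant pairs the statistic is defined as 0 with
#' p = 1 and the result is marked degenerate.
#'
#' @param n12,n21 Non-negative discordant-pair counts.
#' @return An object of class `mcnemar_result` with fields `n12`, `n21`,
#'   `z2`, `p_value`, and `degenerate`.
#' @export
mcnemar <- function(n12, n21) {
  n12 <- as.integer(n12); n21 <- as.integer(n21)
  if (is.na(n12) || is.na(n21) || n12 < 0L || n21 < 0L) {
    stop("discordant counts must be non-negative integers")
  }
  if (n12 + n21 == 0L) {
    z2 <- 0; p <- 1; degenerate <- TRUE
  } else {
    z2 <- (n12 - n21)^2 / (n12 + n21)
    p <- stats::pchisq(z2, df = 1, lower.tail = FALSE)
    degenerate <- FALSE
  }
  structure(list(n12 = n12, n21 = n21, z2 = z2, p_value = p,
                 degenerate = degenerate),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("<mcnemar_result> n12 %d, n21 %d, z2 %.4f, p %.4f%s\n",
              x$n12, x$n21, x$z2, x$p_value,
              if (x$degenerate) " (no discordant pairs)" else ""))
  invisible(x)
}

as_prediction_vector <- function(x, what) {
  if (inherits(x, "eval_result")) {
    stats::setNames(x$predictions$pred, x$predictions$subject_id)
  } else if (!is.null(names(x))) {
    check_labels(x)
  } else {
    stop(what, " must be an eval_result or a named label vector")
  }
}

#' Agreement between manual-interval and detected-interval assessment
#'
#' Builds the discordant-pair table between the classification outcomes
#' obtained from manually annotated intervals and from detected intervals
#' (positive class: deviating), runs the McNemar test, and — when the
#' underlying feature values are supplied — summarizes the paired feature
#' differences with the mean difference and a Wilcoxon signed-rank test.
#'
#' @param manual,detected `eval_result` objects or named prediction vectors
#'   over the same subjects.
#' @param manual_features,detected_features Optional named numeric feature
#'   vectors over the same subjects.
#' @return An object of class `agreement_report`: the `mcnemar_result`,
#'   discordant counts, and (optionally) `feature_diff` with `mean_diff`,
#'   `wilcoxon_statistic`, and `wilcoxon_p`.
#' @export
agreement_report <- function(manual, detected,
                             manual_features = NULL,
                             detected_features = NULL) {
  m <- as_prediction_vector(manual, "manual")
  d <- as_prediction_vector(detected, "detected")
  if (!setequal(names(m), names(d)) || length(m) != length(d)) {
    stop("manual and detected predictions cover different subject sets")
  }
  d <- d[names(m)]
  n12 <- sum(m == "deviating" & d == "normal")
  n21 <- sum(m == "normal" & d == "deviating")
  out <- list(mcnemar = mcnemar(n12, n21), n12 = n12, n21 = n21,
              n = length(m))
  if (!is.null(manual_features) && !is.null(detected_features)) {
    if (!setequal(names(manual_features), names(detected_features))) {
      stop("feature vectors cover different subject sets")
    }
    mf <- manual_features[names(m)]; df_ <- detected_features[names(m)]
    diffs <- df_ - mf
    wt <- if (all(diffs == 0)) {
      list(statistic = c(V = 0), p.value = 1)
    } else {
      suppressWarnings(stats::wilcox.test(df_, mf, paired = TRUE))
    }
    out$feature_diff <- list(mean_diff = mean(diffs),
                             wilcoxon_statistic = unname(wt$statistic),
                             wilcoxon_p = wt$p.value)
  }
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n %d, n12 %d, n21 %d, McNemar p %.4f\n",
              x$n, x$n12, x$n21, x$mcnemar$p_value))
  if (!is.null(x$feature_diff)) {
    cat(sprintf("  paired feature mean difference %.4f (Wilcoxon p %.4f)\n",
                x$feature_diff$mean_diff, x$feature_diff$wilcoxon_p))
  }
  invisible(x)
}
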