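test_that("k-NN votes among the nearest neighbors with unbiased ties", {
  train <- c(rep(1.0, 10), rep(3.0, 5))
  labels <- rep(c("normal", "deviating"), c(10, 5))
  spec <- classifier_spec("knn", knn_k = 5)
  out <- fit_predict(spec, train, labels, c(3.0, 1.0, 2.2))
  expect_equal(out$label, c("deviating", "normal", "deviating"))
  expect_equal(out$score[1], 1)      # all five neighbors at 3.0 are deviating
  expect_equal(out$score[2], 0)
  expect_error(fit_predict(spec, rep(1, 5), rep("normal", 5), 2), "both classes")
  expect_error(classifier_spec("knn", knn_k = 4), "odd")
})

test_that("the one-class SVM flags out-of-distribution features", {
  set.seed(15)
  train <- c(1 + rnorm(30, sd = 0.01), 2.5, 3.1)
  labels <- rep(c("normal", "deviating"), c(30, 2))
  spec <- classifier_spec("one_class_svm", ocsvm_nu = 0.1)
  out <- fit_predict(spec, train, labels, c(3.0, 1.0))
  expect_equal(out$label[1], "deviating")
  expect_equal(out$label[2], "normal")
  expect_gt(out$score[1], out$score[2])   # larger score = more deviating
  expect_error(fit_predict(spec, c(2, 3), rep("deviating", 2), 1),
               "normal-class")
})

test_that("LDA places its boundary between well-separated class means", {
  set.seed(16)
  train <- c(rnorm(40, 0, 0.3), rnorm(40, 4, 0.3))
  labels <- rep(c("normal", "deviating"), each = 40)
  spec <- classifier_spec("lda")
  out <- fit_predict(spec, train, labels, c(0.2, 3.8, 1.9, 2.1))
  expect_equal(out$label, c("normal", "deviating", "normal", "deviating"))
  # posterior for deviating increases monotonically across the boundary
  expect_true(all(diff(out$score[c(1, 3, 4, 2)]) > 0))
  expect_error(fit_predict(spec, rnorm(5), rep("normal", 5), 0), "both classes")
})

test_that("LOSO assessment pools held-out predictions correctly", {
  # perfect separation
  f <- c(rep(1, 8), rep(4, 4))
  l <- rep(c("normal", "deviating"), c(8, 4))
  res <- loso_assess(f, l, classifier_spec("knn"))
  expect_equal(res$accuracy, 1)
  expect_equal(res$auc, 1)
  expect_equal(res$tp + res$tn + res$fp + res$fn, 12L)
  expect_equal(res$accuracy, (res$tp + res$tn) /
                 (res$tp + res$tn + res$fp + res$fn))

  # accuracy invariant to subject ordering
  set.seed(20)
  perm <- sample(12)
  res_p <- loso_assess(f[perm], l[perm], classifier_spec("knn"))
  expect_equal(res_p$accuracy, res$accuracy)

  # the held-out subject is genuinely excluded: with 1-NN on alternating
  # labels the nearest training neighbor always has the opposite label
  f2 <- 1:6
  l2 <- rep(c("normal", "deviating"), 3)
  res2 <- loso_assess(f2, l2, classifier_spec("knn", knn_k = 1))
  expect_equal(res2$accuracy, 0)

  expect_error(loso_assess(1, "normal", classifier_spec("knn")), "at least 2")
  expect_error(loso_assess(c(1, 2), c("normal", "normal"),
                           classifier_spec("knn")), "both classes")
})

test_that("k-NN beats the majority-class rate on calibrated cohorts", {
  draw <- synth_features("turn_360", 48, 11, seed = 2)
  res <- loso_assess(draw$features, draw$labels, classifier_spec("knn"))
  expect_gt(res$accuracy, 48 / 59)
})

test_that("label-shuffled features give chance-level AUC", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    f <- rnorm(40)
    l <- sample(rep(c("normal", "deviating"), 20))
    loso_assess(f, l, classifier_spec("knn"))$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("detection accuracy is per-sample indicator agreement", {
  a <- motion_interval(3, 6, "detected")
  expect_equal(detection_accuracy(a, motion_interval(3, 6), 12, 40), 1)
  got <- detection_accuracy(motion_interval(4, 7, "detected"),
                            motion_interval(3, 6), 12, 40)
  expect_equal(got, 400 / 480)
})

test_that("ROC AUC equals exhaustive pair counting", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8),
                       c("normal", "normal", "deviating", "deviating")), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), rep(c("normal", "deviating"), 2)), 0.75)
  expect_equal(roc_auc(rep(0.3, 6), rep(c("normal", "deviating"), 3)), 0.5)
  expect_error(roc_auc(1:3, rep("normal", 3)), "both classes")

  for (s in 1:50) {
    set.seed(s)
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- sample(c("normal", "deviating"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("normal", "deviating")
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels),
                 info = paste("seed", s))
  }
})

test_that("ROC AUC matches an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(30)
  scores <- rnorm(60)
  labels <- sample(c("normal", "deviating"), 60, replace = TRUE)
  labels[1:2] <- c("normal", "deviating")
  oracle <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(labels == "deviating", scores, direction = "<"))))
  expect_equal(roc_auc(scores, labels), oracle, tolerance = 1e-12)
})

test_that("McNemar statistic follows the discordant-count formula", {
  m <- mcnemar(4, 4)
  expect_equal(m$z2, 0)
  expect_equal(m$p_value, 1)
  m2 <- mcnemar(5, 1)
  expect_equal(m2$z2, 16 / 6, tolerance = 1e-12)
  expect_equal(m2$p_value, stats::pchisq(16 / 6, 1, lower.tail = FALSE))
  m3 <- mcnemar(0, 0)
  expect_true(m3$degenerate)
  expect_equal(m3$p_value, 1)
  # symmetry
  expect_equal(mcnemar(7, 2)$z2, mcnemar(2, 7)$z2)
  expect_equal(mcnemar(7, 2)$p_value, mcnemar(2, 7)$p_value)
  expect_error(mcnemar(-1, 2), "non-negative")
})

test_that("agreement reports count discordant pairs against brute force", {
  ids <- sprintf("S%02d", 1:10)
  a <- stats::setNames(rep(c("normal", "deviating"), 5), ids)
  expect_equal(agreement_report(a, a)$mcnemar$p_value, 1)
  expect_equal(agreement_report(a, a)$n12, 0L)

  b <- a; b["S01"] <- "deviating"   # one manual-normal, detected-deviating
  rep1 <- agreement_report(a, b)
  expect_equal(rep1$n21, 1L)
  expect_equal(rep1$mcnemar$z2, 1)

  set.seed(31)
  m <- stats::setNames(sample(c("normal", "deviating"), 30, TRUE),
                       sprintf("S%02d", 1:30))
  d <- stats::setNames(sample(c("normal", "deviating"), 30, TRUE),
                       sprintf("S%02d", 1:30))
  rep2 <- agreement_report(m, d)
  expect_equal(rep2$n12 + rep2$n21, sum(m != d))

  expect_error(agreement_report(a, a[1:5]), "different subject sets")

  fa <- stats::setNames(rnorm(10, 2), ids)
  fb <- fa + 0.3
  rep3 <- agreement_report(a, a, fa, fb)
  expect_equal(rep3$feature_diff$mean_diff, 0.3, tolerance = 1e-12)
  expect_lt(rep3$feature_diff$wilcoxon_p, 0.01)
})
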