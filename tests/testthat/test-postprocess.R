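test_that("local-maximum finder handles plateaus, height, and separation", {
  x <- c(0, 1, 0, 2, 2, 2, 0, 0.4, 0, 3, 0)
  expect_equal(find_local_maxima(x), c(2L, 5L, 8L, 10L))
  expect_equal(find_local_maxima(x, min_height = 0.5), c(2L, 5L, 10L))
  # separation keeps the higher of two close peaks
  y <- c(0, 1, 0.9, 0.95, 0, 0, 0, 0.8, 0)
  expect_equal(find_local_maxima(y, min_sep = 3L), c(2L, 8L))
  # endpoints are never peaks
  expect_equal(find_local_maxima(c(5, 1, 1, 1, 6)), integer(0))
})

test_that("mean filtering matches hand-computed averages and conserves range", {
  n <- 101
  t <- (seq_len(n) - 1) * 0.025

  const <- probability_trace(t, rep(0.3, n))
  expect_equal(smooth_trace(const, 1.0)$p_task, rep(0.3, n))

  imp <- rep(0, n); imp[51] <- 1
  sm <- smooth_trace(probability_trace(t, imp), 0.25)  # 10 steps
  expect_equal(max(sm$p_task), 1 / 10)

  step_tr <- probability_trace(t, rep(c(0, 1), c(50, 51)))
  sm9 <- smooth_trace(step_tr, 0.225)                  # 9 steps, odd
  # hand-computed centered average at the first 1-valued sample: 5 of 9
  expect_equal(sm9$p_task[51], 5 / 9)
  expect_equal(sm9$p_task[50], 4 / 9)

  set.seed(10)
  tr <- random_trace(300, seed = 10)
  smr <- smooth_trace(tr, 1.0)
  expect_true(all(abs(smr$p_task + smr$p_nontask - 1) < 1e-9))
  expect_gte(min(smr$p_task), min(tr$p_task) - 1e-12)
  expect_lte(max(smr$p_task), max(tr$p_task) + 1e-12)

  expect_error(smooth_trace(probability_trace(t[1:5], rep(0.2, 5)), 1.0),
               "longer than")
})

test_that("smoothing agrees with zoo's partial rolling mean", {
  skip_if_not_installed("zoo")
  tr <- random_trace(200, seed = 17)
  sm <- smooth_trace(tr, 1.0)
  # 40 steps is even: our window spans 19 back / 20 forward
  oracle <- vapply(seq_len(200), function(i) {
    idx <- max(1, i - 19):min(200, i + 20)
    mean(tr$p_task[idx])
  }, 0)
  oracle_n <- vapply(seq_len(200), function(i) {
    idx <- max(1, i - 19):min(200, i + 20)
    mean(tr$p_nontask[idx])
  }, 0)
  expect_equal(sm$p_task, oracle / (oracle + oracle_n), tolerance = 1e-12)
})

test_that("candidate intervals anchor at nontask peaks around the crossings", {
  # piecewise-linear trace: nontask maxima at 3.2 s and 6.8 s, task
  # probability above 0.5 on (3.5, 6.5)
  t <- seq(0, 10, by = 0.025)
  pn <- approx(x = c(0, 0.5, 3.2, 3.35, 3.8, 6.2, 6.65, 6.8, 7.0, 10),
               y = c(0.88, 0.9, 0.96, 0.9, 0.05, 0.05, 0.9, 0.96, 0.9, 0.88),
               xout = t)$y
  tr <- probability_trace(t, 1 - pn, pn)
  cands <- candidate_intervals(tr)
  expect_length(cands$intervals, 1L)
  expect_equal(cands$intervals[[1]]$start_s, 3.2)
  expect_equal(cands$intervals[[1]]$end_s, 6.8)
  expect_false(cands$intervals[[1]]$degenerate_flag)

  # no crossing at all -> empty candidate set
  flat <- probability_trace(t, rep(0.2, length(t)))
  expect_length(candidate_intervals(flat)$intervals, 0L)

  # two separate excursions -> two time-ordered intervals
  pn2 <- approx(x = c(0, 1.0, 1.2, 2.0, 3.0, 3.2, 4.0, 5.0, 5.2, 6.0, 10),
                y = c(0.9, 0.97, 0.9, 0.1, 0.9, 0.97, 0.1, 0.9, 0.97, 0.9, 0.88),
                xout = t)$y
  tr2 <- probability_trace(t, 1 - pn2, pn2)
  cands2 <- candidate_intervals(tr2)
  expect_length(cands2$intervals, 2L)
  expect_lt(cands2$intervals[[1]]$end_s, cands2$intervals[[2]]$start_s + 1e-9)

  # missing peak on one side falls back to the crossing and flags it
  pn3 <- approx(x = c(0, 4, 6, 10), y = c(1, 1, 0, 0), xout = t)$y
  tr3 <- probability_trace(t, 1 - pn3, pn3)
  cands3 <- candidate_intervals(tr3)
  expect_length(cands3$intervals, 1L)
  expect_true(cands3$intervals[[1]]$degenerate_flag)
})

test_that("candidate intervals equal a brute-force rule scan on random traces", {
  for (s in 1:200) {
    tr <- random_trace(sample(c(50:500), 1), seed = s)
    got <- candidate_intervals(tr)$intervals
    want <- brute_candidates(tr)
    expect_equal(length(got), length(want), info = paste("seed", s))
    for (j in seq_along(want)) {
      expect_equal(got[[j]]$start_s, unname(want[[j]]["start"]),
                   info = paste("seed", s))
      expect_equal(got[[j]]$end_s, unname(want[[j]]["end"]),
                   info = paste("seed", s))
      expect_equal(got[[j]]$degenerate_flag, unname(want[[j]]["degen"]) == 1,
                   info = paste("seed", s))
    }
  }
})

test_that("interval selection applies the task rules and ignores ordering", {
  fs <- 40; n <- 480
  ap <- rep(0, n); ap[150] <- 2; ap[151] <- -3   # AP range 5 in [3, 4.5] s
  ap[320] <- 1; ap[321] <- -1                    # AP range 2 in [7.5, 9] s
  accel <- rbind(ap, 0, 0)
  yaw <- rep(0, n)
  yaw[120:200] <- 350 * fs / 81                  # ~350 degrees in [3, 5] s
  yaw[280:440] <- 710 * fs / 161                 # ~710 degrees in [7, 11] s
  rec <- make_recording(accel, rbind(0, 0, yaw))
  pre <- preprocess_signals(rec)
  iv_a <- motion_interval(3.0, 4.9, "detected")
  iv_b <- motion_interval(6.9, 11.2, "detected")
  mk <- function(ivs) structure(list(intervals = ivs, trace = NULL),
                                class = "candidate_set")

  sel <- select_interval(mk(list(iv_a, iv_b)), pre, "sit_to_stand")
  expect_equal(sel$start_s, 3.0)               # the larger-AP-range one
  sel_r <- select_interval(mk(list(iv_b, iv_a)), pre, "sit_to_stand")
  expect_equal(sel_r$start_s, sel$start_s)

  sel_t <- select_interval(mk(list(iv_a, iv_b)), pre, "turn_360")
  expect_equal(sel_t$start_s, 3.0)             # the < 360-degree one
  sel_t2 <- select_interval(mk(list(iv_b, iv_a)), pre, "turn_360")
  expect_equal(sel_t2$start_s, 3.0)

  one <- select_interval(mk(list(iv_b)), pre, "turn_360")
  expect_identical(one, iv_b)

  none <- select_interval(mk(list()), pre, "sit_to_stand")
  expect_true(none$degenerate_flag)
  expect_equal(none$start_s, 0)
  expect_equal(none$end_s, recording_duration(rec))
})

test_that("full detection is deterministic and flags idle-only recordings", {
  params <- synth_params(pre_idle_s = c(1.5, 2), post_idle_s = c(1.5, 2),
                         task_duration_s = c(1.5, 2))
  cohort <- synth_cohort("sit_to_stand", 3, 1, params, seed = 6)
  windows <- lapply(cohort, function(it) {
    make_windows(preprocess_signals(it$recording), it$label$interval,
                 step_s = 0.1)
  })
  det <- train_detector(build_detector(tiny_detector_config(
    conv_filters = 8L, lstm_units = 12L)), windows)
  cfg <- pipeline_config(mean_filter_s = 1.0)

  rec <- cohort[[1]]$recording
  iv1 <- detect_motion(rec, det, cfg)
  iv2 <- detect_motion(rec, det, cfg)
  expect_identical(iv1, iv2)
  expect_s3_class(iv1, "motion_interval")

  # idle-only recording: no crossing, whole-recording fallback
  set.seed(99)
  idle <- make_recording(matrix(rnorm(3 * 200, sd = 0.05), 3),
                         matrix(rnorm(3 * 200, sd = 1), 3))
  iv_idle <- detect_motion(idle, det, cfg)
  expect_true(iv_idle$degenerate_flag)
})
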