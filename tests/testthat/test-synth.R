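test_that("generation is deterministic under a fixed seed", {
  a <- synth_recording("turn_360", "deviating", seed = 5)
  b <- synth_recording("turn_360", "deviating", seed = 5)
  expect_identical(a$recording$accel, b$recording$accel)
  expect_identical(a$recording$gyro, b$recording$gyro)
  expect_identical(a$label$interval$start_s, b$label$interval$start_s)
  c <- synth_recording("turn_360", "deviating", seed = 6)
  expect_false(identical(a$recording$accel, c$recording$accel))
})

test_that("cohorts have the requested composition and valid recordings", {
  coh <- synth_cohort("sit_to_stand", 45, 14, seed = 0)
  expect_length(coh, 59L)
  conds <- vapply(coh, function(it) it$label$condition, "")
  expect_equal(sum(conds == "deviating"), 14L)
  expect_false(anyDuplicated(names(coh)) > 0)

  coh2 <- synth_cohort("turn_360", 48, 11, seed = 1)
  expect_length(coh2, 59L)
  expect_equal(sum(vapply(coh2, function(it) it$label$condition, "") ==
                     "deviating"), 11L)

  single <- synth_cohort("stand_to_sit", 1, 0, seed = 2)
  expect_length(single, 1L)
  expect_equal(single[[1]]$label$condition, "normal")
  expect_error(synth_cohort("sit_to_stand", 0, 0), "at least one")

  for (it in coh[1:5]) {
    expect_s3_class(validate_recording(it$recording), "imu_recording")
    iv <- it$label$interval
    dur <- recording_duration(it$recording)
    expect_gte(iv$start_s, 1)            # >= 1 s of nontask on each side
    expect_lte(iv$end_s, dur - 1)
  }
})

test_that("noiseless templates reproduce the drawn feature values", {
  # sit/stand: forcing the attempt table forces the peak count exactly
  for (k in 1:4) {
    tab <- stats::setNames(1, as.character(k))
    p <- quiet_params(attempts = list(
      sit_to_stand = list(normal = tab, deviating = tab),
      stand_to_sit = list(normal = tab, deviating = tab)))
    for (task in c("sit_to_stand", "stand_to_sit")) {
      out <- synth_recording(task, "normal", p, seed = 30 + k)
      pre <- preprocess_signals(out$recording)
      count <- ap_peak_count(pre$accel_detrended[1, ], out$label$interval,
                             out$recording$sampling_rate_hz)
      expect_equal(count, k)
    }
  }
  # turning: recovered mean speed within 5 % of the generating speed
  for (s in 1:6) {
    out <- synth_recording("turn_360", if (s %% 2) "normal" else "deviating",
                           quiet_params(), seed = 100 + s)
    pre <- preprocess_signals(out$recording)
    speed <- mean_turn_speed(pre$ang_disp[3, ], out$label$interval,
                             out$recording$sampling_rate_hz)
    drawn <- 360 / interval_duration(out$label$interval)
    expect_lt(abs(speed - drawn) / drawn, 0.05)
  }
})

test_that("a forced 60 deg/s turn lasts 6 s and accumulates 360 degrees", {
  p <- quiet_params(turn_speed = list(
    normal = list(mean = 60, sd = 0, min = 60, max = 60),
    deviating = list(mean = 60, sd = 0, min = 60, max = 60)),
    turn_ramp_frac = 0.01)
  out <- synth_recording("turn_360", "normal", p, seed = 3)
  expect_lt(abs(interval_duration(out$label$interval) - 6), 0.1)
  yaw <- sum(out$recording$gyro[3, ]) / out$recording$sampling_rate_hz
  expect_lt(abs(yaw - 360), 1e-6)
})

test_that("synthetic feature draws follow the configured distributions", {
  # degenerate categorical table
  d <- list(normal = list(type = "categorical", probs = c("1" = 1)),
            deviating = list(type = "categorical", probs = c("2" = 1)))
  out <- synth_features("sit_to_stand", 10, 3, d, seed = 4)
  expect_equal(out$features, c(rep(1, 10), rep(2, 3)))
  expect_equal(out$labels, rep(c("normal", "deviating"), c(10, 3)))

  # identical seeds give identical draws
  a <- synth_features("turn_360", 20, 20, seed = 9)
  b <- synth_features("turn_360", 20, 20, seed = 9)
  expect_identical(a$features, b$features)

  # truncated-normal healthy turning speeds: mean within 1 deg/s of 58.16,
  # cross-checked against the closed-form truncated-normal mean
  big <- synth_features("turn_360", 10000, 0, seed = 1)
  expect_lt(abs(mean(big$features) - 58.16), 1)
  mu <- 58.16; sig <- 19.22
  a_ <- (20 - mu) / sig; b_ <- (100 - mu) / sig
  closed <- mu + sig * (stats::dnorm(a_) - stats::dnorm(b_)) /
    (stats::pnorm(b_) - stats::pnorm(a_))
  expect_lt(abs(mean(big$features) - closed), 0.5)
  expect_true(all(big$features >= 20 & big$features <= 100))

  # one-sample KS test against the truncated-normal cdf at alpha = 0.01
  ptrunc <- function(q) {
    (stats::pnorm((q - mu) / sig) - stats::pnorm(a_)) /
      (stats::pnorm(b_) - stats::pnorm(a_))
  }
  ks <- suppressWarnings(stats::ks.test(big$features, ptrunc))
  expect_gt(ks$p.value, 0.01)

  # chi-squared test of a categorical table at alpha = 0.01
  tab <- c("1" = 0.2, "2" = 0.4, "3" = 0.25, "4" = 0.15)
  dd <- list(normal = list(type = "categorical", probs = tab),
             deviating = list(type = "categorical", probs = tab))
  draws <- synth_features("sit_to_stand", 2000, 0, dd, seed = 2)$features
  counts <- table(factor(draws, levels = 1:4))
  chi <- stats::chisq.test(counts, p = tab)
  expect_gt(chi$p.value, 0.01)
})

test_that("malformed generator parameters are rejected", {
  expect_error(synth_params(ap_pulse_amp = c(2, 1)), "range")
  expect_error(synth_params(attempts = list(
    sit_to_stand = list(normal = c("1" = 0.5), deviating = c("1" = 1)),
    stand_to_sit = list(normal = c("1" = 1), deviating = c("1" = 1)))),
    "sum to 1")
  expect_error(synth_params(attempts = list(
    sit_to_stand = list(normal = c("1" = 0), deviating = c("1" = 1)),
    stand_to_sit = list(normal = c("1" = 1), deviating = c("1" = 1)))),
    "positive total")
  expect_error(synth_features("sit_to_stand", 5, 5,
                              list(normal = list(type = "nope"),
                                   deviating = list(type = "nope"))),
               "type")
})
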