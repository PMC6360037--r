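test_that("subsampling decimates frames and divides the frame rate", {
  tr <- random_trial(nf = 200L, frame_rate = 100)
  s <- subsample(tr, 2L)
  expect_identical(n_frames(s), 100L)
  expect_equal(s$frame_rate, 50)
  expect_equal(s$positions[2, , ], tr$positions[3, , ])  # frame 2 was index 2

  expect_identical(subsample(tr, 1L), tr)

  odd <- random_trial(nf = 101L)
  s2 <- subsample(odd, 2L)
  expect_identical(n_frames(s2), 51L)
  expect_equal(s2$positions, odd$positions[seq(1, 101, 2), , ])

  expect_error(subsample(tr, 0L), "positive")
})

test_that("subsampling by a then b equals subsampling by a*b", {
  tr <- random_trial(nf = 240L, seed = 3L)
  for (ab in list(c(2L, 3L), c(3L, 2L), c(2L, 2L))) {
    two_step <- subsample(subsample(tr, ab[1]), ab[2])
    one_step <- subsample(tr, ab[1] * ab[2])
    expect_equal(two_step$positions, one_step$positions)
    expect_equal(two_step$frame_rate, one_step$frame_rate)
  }
})

test_that("consecutive same-side strikes are spaced one stride apart", {
  pat <- patient_with_period(1.0, seed = 2L)
  g <- generate_trial(pat, 8, noise_sd = 1, seed = 5L)
  sub <- subsample(g$trial, 2L)
  ev <- detect_gait_events(sub)
  fr <- sub$frame_rate
  for (side in list(ev$left_strikes, ev$right_strikes)) {
    gaps <- diff(side) / fr
    expect_true(all(abs(gaps - 2.0) <= 1 / fr + 1e-9))
  }
})

test_that("a standing trial yields an insufficient-steps error", {
  expect_error(detect_gait_events(standing_trial()), "insufficient steps")
})

test_that("detected strikes match simulator ground truth within 3 frames", {
  set.seed(10)
  hits <- 0L; total <- 0L
  for (i in 1:12) {
    pat <- synth_patient(sprintf("ev%d", i), sample(1:4, 1))
    g <- generate_trial(pat, 8, noise_sd = 2, seed = 100 + i)
    sub <- subsample(g$trial, 2L)
    ev <- detect_gait_events(sub)
    for (gt in round(g$events$left_strikes / 2)) {
      total <- total + 1L
      if (min(abs(ev$left_strikes - gt)) <= 3) hits <- hits + 1L
    }
    for (gt in round(g$events$right_strikes / 2)) {
      total <- total + 1L
      if (min(abs(ev$right_strikes - gt)) <= 3) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("trimming keeps whole steps and derives the average period", {
  tr <- random_trial(nf = 600L, frame_rate = 50)
  # hand-made events: 11 strikes spanning exactly 10 s -> 10 steps of 1 s
  strikes <- seq(0L, 500L, by = 50L)
  ev <- gait_events(strikes[seq(1, 11, 2)], strikes[seq(2, 10, 2)],
                    n_frames = 600L)
  out <- trim_to_complete_steps(tr, ev)
  expect_identical(out$steps$n_steps, 10L)
  expect_equal(out$steps$period_T, 1.0)
  expect_identical(n_frames(out$trial), 501L)

  # a span of exactly one step
  ev1 <- gait_events(10L, 60L, n_frames = 600L)
  out1 <- trim_to_complete_steps(tr, ev1)
  expect_identical(out1$steps$n_steps, 1L)
  expect_equal(out1$steps$period_T, 1.0)
})

test_that("trimming a simulated trial recovers the scripted step count", {
  pat <- patient_with_period(1.0, seed = 4L)
  # 7.3 s at period 1.0 with a random start phase -> 6 whole scripted steps
  g <- generate_trial(pat, 7.3, noise_sd = 1, seed = 9L)
  sub <- subsample(g$trial, 2L)
  out <- trim_to_complete_steps(sub, detect_gait_events(sub))
  n_truth <- length(c(g$events$left_strikes, g$events$right_strikes)) - 1L
  expect_equal(out$steps$n_steps, n_truth, tolerance = 0)
  expect_lt(abs(n_frames(out$trial) / sub$frame_rate -
                n_truth * 1.0), 2 / sub$frame_rate + 1e-9)
})

test_that("recovered step period stays within 5% of the scripted period", {
  set.seed(20)
  err <- vapply(1:100, function(i) {
    pat <- synth_patient(sprintf("pp%d", i), sample(1:4, 1))
    g <- generate_trial(pat, 7, noise_sd = 1, seed = 2000 + i)
    sub <- subsample(g$trial, 2L)
    out <- trim_to_complete_steps(sub, detect_gait_events(sub))
    abs(out$steps$period_T - pat$period) / pat$period
  }, numeric(1))
  expect_lt(max(err), 0.05)
})

test_that("hand-annotated events can be injected through the CSV sidecar", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(side = c("left", "right", "left"),
                              event = c("strike", "strike", "toeoff"),
                              frame = c(10L, 60L, 35L)),
                   f, row.names = FALSE)
  ev <- read_events_csv(f, n_frames = 100L)
  expect_identical(ev$left_strikes, 10L)
  expect_identical(ev$right_strikes, 60L)
  expect_identical(ev$left_toeoffs, 35L)
})
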