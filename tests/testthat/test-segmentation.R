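test_that("initial step duration matches the periodicity of built signals", {
  fs <- 50
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  set.seed(42)
  # impulse train, period 0.6 s, with measurement noise
  x <- numeric(length(t)); x[seq(1, length(t), by = 0.6 * fs)] <- 2
  x <- x + rnorm(length(t), sd = 0.1)
  expect_equal(estimate_initial_step_duration(x, fs), 0.6, tolerance = 0.02 / 0.6)
  # 2 Hz sinusoid: analytic period 0.5 s
  expect_equal(estimate_initial_step_duration(sin(2 * pi * 2 * t), fs), 0.5,
               tolerance = 0.02 / 0.5)
  expect_error(estimate_initial_step_duration(numeric(length(t)), fs),
               "no periodicity")
})

test_that("strike detection recovers generator ground truth", {
  # frame-exact at zero noise
  sim0 <- simulate_participant(short_params(120, noise_sd = zero_noise()),
                               seed = 3)
  st0 <- detect_foot_strikes(sim0$recording)
  expect_identical(st0$strikes$frame, sim0$truth$strikes$frame)
  expect_true(all(diff(st0$strikes$frame) > 0))
  # >= 95% of true strikes matched within +/-3 frames at default noise
  sim <- simulate_participant(short_params(120), seed = 8)
  st <- detect_foot_strikes(sim$recording)
  nearest <- vapply(sim$truth$strikes$frame,
                    function(f) min(abs(st$strikes$frame - f)), 1)
  expect_gte(mean(nearest <= 3), 0.95)
  # inter-strike intervals inside the admissible band once converged
  iv <- diff(st$strikes$time)
  expect_true(all(iv >= 0.3 - 1e-9 & iv <= 1.5 + 1e-9))
})

test_that("sides alternate and are seeded from ML polarity", {
  sim0 <- simulate_participant(short_params(60, noise_sd = zero_noise()),
                               seed = 3)
  st <- detect_foot_strikes(sim0$recording)
  expect_true(all(st$strikes$side[-1] != head(st$strikes$side, -1)))
  ml0 <- sim0$recording$channels$acc_ml[st$strikes$frame[1]]
  expect_identical(st$strikes$side[1], if (ml0 >= 0) "right" else "left")
})

test_that("a missing impact still yields a strike inside the search band", {
  fs <- 50; n <- 30 * fs
  t <- (0:(n - 1)) / fs
  ap <- 0.1 * sin(2 * pi * 2 * t)            # small background periodicity
  impacts <- seq(26, n, by = 25)             # strikes every 0.5 s
  drop_at <- impacts[30]
  for (f in setdiff(impacts, drop_at)) ap[f] <- ap[f] + 2
  rec <- toy_recording(n = n, acc_ap = ap, acc_ml = 0.3 * sin(2 * pi * t))
  st <- detect_foot_strikes(rec)
  # no gap: some local peak is emitted where the impact went missing
  expect_true(all(diff(st$strikes$frame) <= ceiling(1.5 * 0.5 * fs)))
  expect_true(any(abs(st$strikes$frame - drop_at) <= 0.25 * fs))
})

test_that("flat AP acceleration raises an insufficient-steps error", {
  rec <- toy_recording(n = 3000, acc_ap = rep(0, 3000))
  expect_error(detect_foot_strikes(rec), "no periodicity|insufficient steps")
  # weak periodicity but no acceptable peaks -> insufficient steps
  t <- (0:2999) / 50
  rec2 <- toy_recording(n = 3000, acc_ap = c(sin(2 * pi * 2 * t[1:200]),
                                             rep(0, 2800)))
  expect_error(detect_foot_strikes(rec2), "insufficient steps")
})

test_that("manual corrections edit, validate and invert cleanly", {
  sim <- simulate_participant(short_params(60, noise_sd = zero_noise()),
                              seed = 5)
  st <- detect_foot_strikes(sim$recording)
  gap_frame <- st$strikes$frame[10] + 13L
  edited <- apply_manual_corrections(
    st, list(list(op = "add", frame = gap_frame, side = "left")),
    recording = sim$recording)
  expect_equal(nrow(edited$strikes), nrow(st$strikes) + 1)
  expect_true(all(diff(edited$strikes$frame) > 0))
  expect_identical(edited$strikes$source[edited$strikes$frame == gap_frame],
                   "manual")
  # add then remove restores the original frames
  restored <- apply_manual_corrections(
    edited, list(list(op = "remove", frame = gap_frame)),
    recording = sim$recording)
  expect_identical(restored$strikes$frame, st$strikes$frame)
  # move changes only that strike
  moved <- apply_manual_corrections(
    st, list(list(op = "move", frame = st$strikes$frame[5], to = st$strikes$frame[5] + 2L)),
    recording = sim$recording)
  expect_equal(moved$strikes$frame[5], st$strikes$frame[5] + 2L)
  expect_identical(moved$strikes$frame[-5], st$strikes$frame[-5])
  # invalid edits
  expect_error(apply_manual_corrections(
    st, list(list(op = "add", frame = st$strikes$frame[2]))), "duplicate")
  expect_error(apply_manual_corrections(
    st, list(list(op = "remove", frame = 1L))), "no strike")
  # edits can arrive as a JSON file
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(op = "add", frame = gap_frame,
                                 side = "left")), path, auto_unbox = TRUE)
  from_file <- apply_manual_corrections(st, path, recording = sim$recording)
  expect_identical(from_file$strikes$frame, edited$strikes$frame)
})

test_that("a yaw-rate boxcar with 180 degrees net rotation is one turn", {
  n <- 3000
  yaw <- numeric(n)
  yaw[1000:1150] <- 60          # 151 frames * 60 deg/s / 50 Hz = 181 deg
  rec <- toy_recording(n = n, av_rotation = yaw)
  tu <- detect_turn_intervals(rec)
  expect_equal(nrow(tu), 1)
  expect_lte(abs(tu$center_frame - 1075), 1)  # midframe of a symmetric boxcar
  expect_gt(tu$net_rotation, 160)
  expect_lt(tu$net_rotation, 190)
  # zero rotation -> no turns
  expect_equal(nrow(detect_turn_intervals(toy_recording(n = n))), 0)
  # sub-threshold net rotation is rejected
  yaw2 <- numeric(n); yaw2[1000:1050] <- 30   # ~30 degrees only
  expect_equal(nrow(detect_turn_intervals(toy_recording(n = n,
                                                        av_rotation = yaw2))),
               0)
})

test_that("six-minute walk yields one turn per walkway length", {
  sim <- simulate_participant(seed = 12)   # defaults: 360 s, 0.8 m/s, 20 m
  tu <- detect_turn_intervals(sim$recording)
  expected <- floor(360 * 0.8 / 20)
  expect_lte(abs(nrow(tu) - expected), 1)
  expect_equal(nrow(sim$truth$turns), expected)
})

test_that("five steps around each turn center are labeled turn", {
  mk_steps <- function(n_strikes, step = 100L)
    step_sequence(data.frame(frame = seq(1L, by = step, length.out = n_strikes),
                             time = seq(0, by = step / 50, length.out = n_strikes),
                             side = rep(c("left", "right"),
                                        length.out = n_strikes),
                             source = "auto"))
  steps <- mk_steps(21)         # 20 steps
  # center inside step 10's window [901, 1001)
  turns <- data.frame(start_frame = 850L, end_frame = 1050L,
                      center_frame = 950L, net_rotation = 180)
  lab <- label_steps(steps, turns)
  expect_identical(which(lab$labels == "turn"), 8:12)
  expect_equal(sum(lab$labels == "straight"), 15)
  expect_equal(lab$truncated_turns, 0L)
  # no turns -> everything straight
  lab0 <- label_steps(steps, turns[0, ])
  expect_true(all(lab0$labels == "straight"))
  # center in step 2's window: window clipped at the start, flagged
  turns_edge <- data.frame(start_frame = 100L, end_frame = 200L,
                           center_frame = 150L, net_rotation = 180)
  lab_e <- label_steps(steps, turns_edge)
  expect_identical(which(lab_e$labels == "turn"), 1:4)
  expect_equal(lab_e$truncated_turns, 1L)
  # center outside all step windows is skipped with a warning
  turns_out <- data.frame(start_frame = 2150L, end_frame = 2250L,
                          center_frame = 2200L, net_rotation = 180)
  expect_warning(lab_o <- label_steps(steps, turns_out), "outside")
  expect_true(all(lab_o$labels == "straight"))
})

test_that("non-truncated turns contribute exactly five turn steps", {
  sim <- simulate_participant(short_params(180), seed = 21)
  out <- process_recording(sim$recording)
  n_turns <- nrow(out$turns)
  expect_gt(n_turns, 0)
  runs <- rle(out$steps$labels)
  turn_runs <- runs$lengths[runs$values == "turn"]
  expect_true(all(turn_runs == 5 |
                    seq_along(turn_runs) %in% c(1, length(turn_runs))))
  expect_equal(sum(out$steps$labels == "turn"),
               5 * (n_turns - out$steps$truncated_turns) +
                 sum(turn_runs[turn_runs < 5]))
})
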