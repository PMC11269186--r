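test_that("foot distance signal handles degenerate geometries", {
  n <- 90
  still <- matrix(rep(c(0, 0.05, 0), each = n), n)
  rec <- rec_with_feet(still, still)
  d <- foot_distance_signal(rec)
  expect_true(all(d$distance_m == 0))

  apart <- still
  apart[, 1] <- 0.3
  rec2 <- rec_with_feet(still, apart)
  expect_equal(foot_distance_signal(rec2)$distance_m, rep(0.3, n))
  # vertical offset is invisible in the horizontal plane
  up <- apart
  up[, 2] <- 1
  rec3 <- rec_with_feet(still, up)
  expect_equal(foot_distance_signal(rec3)$distance_m, rep(0.3, n))
  expect_equal(
    foot_distance_signal(rec3, plane = "xyz")$distance_m,
    rep(sqrt(0.3^2 + 0.95^2), n)
  )
})

test_that("peaks of a sinusoidal distance signal are located to one frame", {
  fs <- 30
  t <- seq(0, 10, by = 1 / fs)
  n <- length(t)
  left <- matrix(rep(c(0, 0.05, 0), each = n), n)
  right <- left
  right[, 1] <- 0.25 + 0.1 * sin(2 * pi * 1 * t)
  rec <- rec_with_feet(left, right)
  d <- foot_distance_signal(rec)
  ev <- detect_step_events(d, rec)
  # closed form: maxima at t = 0.25 + k; the first and last peaks fall
  # outside the first/last valley and are trimmed
  expected <- 0.25 + 0:9
  expect_gte(nrow(ev), 9)
  offsets <- vapply(ev$time, function(tt) min(abs(expected - tt)), numeric(1))
  expect_lt(max(offsets), 1 / fs + 1e-9)
})

test_that("constant distance signal raises an insufficient-gait error", {
  n <- 90
  still <- matrix(rep(c(0, 0.05, 0), each = n), n)
  apart <- still
  apart[, 1] <- 0.3
  rec <- rec_with_feet(still, apart)
  d <- foot_distance_signal(rec)
  expect_error(detect_step_events(d, rec), "nsufficient gait")
})

test_that("simulator step events are recovered in count and time", {
  sim <- generate_recording(noiseless_walk_params(), seed = 3)
  rec <- lowpass_filter(sim$recording)
  d <- foot_distance_signal(rec)
  ev <- detect_step_events(d, rec)
  gt <- sim$ground_truth
  expect_lte(abs(nrow(ev) - nrow(gt$interior_events)), 1)
  offsets <- vapply(ev$time, function(tt) min(abs(gt$events$time - tt)), numeric(1))
  expect_lte(max(offsets), 2 / rec$sampling_rate + 1e-9)
  # leading feet alternate strictly
  expect_true(all(ev$leading_foot[-1] != ev$leading_foot[-nrow(ev)]))
})

test_that("phase labels reduce to pure support states for static feet", {
  n <- 90
  still <- matrix(rep(c(0, 0.05, 0), each = n), n)
  apart <- still
  apart[, 1] <- 0.3
  rec <- rec_with_feet(still, apart)
  ph <- suppressWarnings(label_phases(rec, speed_threshold = 0.1))
  expect_true(all(ph$support == "double_support"))

  # right foot moving at 1 m/s, left planted -> single support left
  t <- seq(0, (n - 1) / 30, by = 1 / 30)
  moving <- still
  moving[, 3] <- t * 1.0
  rec2 <- rec_with_feet(still, moving, spine_base = cbind(0, 0.95, t))
  ph2 <- label_phases(rec2, speed_threshold = 0.1)
  expect_true(all(ph2$support == "single_support_left"))
  expect_true(all(ph2$left == "stance") && all(ph2$right == "swing"))
})

test_that("phase labels agree with simulator ground truth", {
  sim <- generate_recording(noiseless_walk_params(), seed = 4)
  rec <- lowpass_filter(sim$recording)
  ph <- label_phases(rec)
  gt <- sim$ground_truth$phases
  agree <- (mean(ph$left == gt$left) + mean(ph$right == gt$right)) / 2
  expect_gte(agree, 0.95)
  expect_false(any(ph$support == "flight_artifact"))
})

test_that("gait cycles follow from constructed alternating events", {
  events <- tibble::tibble(
    index = 1:4, time = c(0.5, 1.0, 1.5, 2.0),
    leading_foot = c("left", "right", "left", "right"),
    step_length = c(0.4, 0.4, 0.4, 0.4),
    step_width = 0.1, peak_distance = 0.42, frame = c(15, 30, 45, 60)
  )
  t <- seq(0, 2.5, by = 1 / 30)
  phases <- tibble::tibble(
    time_s = t, left = "stance", right = "stance", support = "double_support"
  )
  d <- tibble::tibble(time_s = t, distance_m = 0.3)
  cycles <- segment_gait_cycles(events, phases, d)
  expect_equal(nrow(cycles), 2)
  expect_equal(cycles$stride_time, c(1, 1))
  expect_equal(cycles$stride_length, c(0.8, 0.8))
})

test_that("cycle durations satisfy stance + swing = stride within a frame", {
  sim <- generate_recording(noiseless_walk_params(), seed = 5)
  rec <- lowpass_filter(sim$recording)
  d <- foot_distance_signal(rec)
  ev <- detect_step_events(d, rec)
  ph <- label_phases(rec)
  cy <- segment_gait_cycles(ev, ph, d)
  expect_true(all(
    abs(cy$stance_time + cy$swing_time - cy$stride_time) <= 1 / rec$sampling_rate + 1e-9
  ))
  expect_true(all(cy$stride_time > 0 & cy$stride_length > 0))
  # stance fraction recovered near the configured 0.60
  expect_lt(abs(mean(cy$stance_time / cy$stride_time) - 0.60), 0.05)
})

test_that("event detection is invariant to rigid translation and yaw rotation", {
  sim <- generate_recording(noiseless_walk_params(), seed = 6)
  rec <- lowpass_filter(sim$recording)
  ang <- 0.7
  rot <- function(r) {
    out <- r
    out$x <- cos(ang) * r$x + sin(ang) * r$z + 5
    out$z <- -sin(ang) * r$x + cos(ang) * r$z - 3
    out
  }
  rec2 <- rot(rec)
  ev1 <- detect_step_events(foot_distance_signal(rec), rec)
  ev2 <- detect_step_events(foot_distance_signal(rec2), rec2)
  expect_equal(ev1$time, ev2$time)
  expect_equal(ev1$step_length, ev2$step_length, tolerance = 1e-6)
  expect_equal(ev1$leading_foot, ev2$leading_foot)
  ph1 <- label_phases(rec)
  ph2 <- label_phases(rec2)
  expect_identical(ph1$support, ph2$support)
})
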