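test_that("identical seeds reproduce byte-identical recordings", {
  p <- walker_params(noise_sd = 0.004)
  a <- generate_recording(p, seed = 71)
  b <- generate_recording(p, seed = 71)
  expect_identical(a$recording, b$recording)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
  c <- generate_recording(p, seed = 72)
  expect_false(identical(a$recording$x, c$recording$x))
})

test_that("emitted recordings satisfy the recording invariants", {
  for (path in c("straight", "oval")) {
    sim <- generate_recording(
      walker_params(path = path, noise_sd = 0.005), seed = 73
    )
    rec <- sim$recording
    expect_s3_class(rec, "skeletal_recording")
    expect_true(all(diff(rec$timestamps) > 0))
    expect_true(all(is.finite(rec$x)))
    expect_gte(length(rec$timestamps), 2 * rec$sampling_rate)
  }
})

test_that("step count follows path length over mean step length", {
  p <- noiseless_walk_params()
  sim <- generate_recording(p, seed = 74)
  expected <- floor(10 / 0.40)
  expect_lte(abs(sim$ground_truth$realized$n_steps - expected), 1)
})

test_that("feet are exactly stationary during ground-truth stance", {
  sim <- generate_recording(noiseless_walk_params(), seed = 75)
  rec <- sim$recording
  gt <- sim$ground_truth$phases
  for (side in c("left", "right")) {
    joint <- if (side == "left") "FootLeft" else "FootRight"
    pos <- cbind(rec$x[, joint], rec$z[, joint])
    stance <- gt[[side]] == "stance"
    moving_in_stance <- stance[-1] & stance[-length(stance)]
    step <- sqrt(rowSums((pos[-1, ] - pos[-nrow(pos), ])^2))
    expect_lt(max(step[moving_in_stance]), 1e-6)
  }
})

test_that("doubling cadence doubles recovered macro velocity", {
  vel <- vapply(c(50, 100), function(cad) {
    sim <- generate_recording(noiseless_walk_params(cadence = cad), seed = 76)
    rec <- lowpass_filter(sim$recording)
    ev <- detect_step_events(foot_distance_signal(rec), rec)
    macro_features(rec, ev)$velocity
  }, numeric(1))
  expect_lt(abs(vel[2] / vel[1] - 2), 0.1)
})

test_that("phase labelling survives 5 mm of sensor noise after filtering", {
  sim <- generate_recording(
    walker_params(noise_sd = 0.005, step_length_sd = 0, step_time_sd = 0,
                  step_width_sd = 0, step_height_sd = 0),
    seed = 77
  )
  rec <- lowpass_filter(sim$recording)
  ph <- label_phases(rec)
  gt <- sim$ground_truth$phases
  agree <- (mean(ph$left == gt$left) + mean(ph$right == gt$right)) / 2
  expect_gte(agree, 0.90)
})

test_that("too short a path cannot form two strides", {
  expect_error(
    generate_recording(walker_params(path_length_m = 0.8), seed = 78),
    "two strides"
  )
})

test_that("cohort generation validates sizes and writes a usable manifest", {
  expect_error(generate_cohort(cohort_config(n_hc = 0), seed = 1), "at least one")
  out_dir <- withr::local_tempdir()
  sim <- generate_cohort(cohort_config(n_hc = 2, n_mci = 2, path = "straight"),
                         seed = 79, out_dir = out_dir)
  expect_equal(nrow(sim$manifest), 4)
  mf <- read_manifest(file.path(out_dir, "manifest.csv"))
  expect_true(all(file.exists(mf$recording_path)))
  rec <- read_recording(mf$recording_path[1], subject_id = mf$subject_id[1])
  expect_s3_class(rec, "skeletal_recording")
  expect_identical(table(sim$manifest$group), table(mf$group))
})

test_that("cohort seeds reproduce identical manifests and features", {
  cfg <- cohort_config(n_hc = 3, n_mci = 3)
  a <- generate_cohort(cfg, seed = 80)
  b <- generate_cohort(cfg, seed = 80)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$recordings, b$recordings)
})

test_that("configured group contrast appears in realized gait parameters", {
  # MCI subjects are configured slower; the realized ground-truth walking
  # speed (cadence x step length) should fall below HC in nearly all seeds
  cfg <- cohort_config(n_hc = 30, n_mci = 25)
  lower <- vapply(1:10, function(s) {
    sim <- generate_cohort(cfg, seed = 900 + s)
    speed <- vapply(sim$ground_truth, function(gt) {
      gt$realized$cadence / 60 * gt$realized$mean_step_length
    }, numeric(1))
    mean(speed[sim$manifest$group == "MCI"]) <
      mean(speed[sim$manifest$group == "HC"])
  }, logical(1))
  expect_gte(sum(lower), 9)
})

test_that("simulated cohorts reproduce the configured velocity contrast end to end", {
  tab <- cached_cohort_features(301)
  hc <- tab$velocity[tab$group == "HC"]
  mci <- tab$velocity[tab$group == "MCI"]
  expect_lt(mean(mci), mean(hc))
  expect_equal(nrow(tab), 55)
  expect_true(all(feature_roster()$feature %in% names(tab)))
})
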