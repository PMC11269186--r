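test_that("variability matches an independent two-pass SD/mean oracle", {
  expect_equal(variability(c(0.5, 0.5, 0.5)), 0)
  expect_equal(variability(c(1, 2, 3)), 50) # mean 2, sample SD 1
  expect_true(is.na(variability(c(1))))
  expect_true(is.na(variability(c(-1, 1)))) # mean ~ 0 is undefined

  two_pass_cv <- function(x) {
    m <- sum(x) / length(x)
    ss <- sum((x - m)^2) / (length(x) - 1)
    100 * sqrt(ss) / m
  }
  withr::with_seed(21, {
    for (i in 1:200) {
      x <- runif(sample(2:40, 1), min = 0.1, max = 10)
      expect_equal(variability(x), two_pass_cv(x), tolerance = 1e-9)
    }
  })
})

test_that("symmetry index matches direct arithmetic and stays in [0, 1]", {
  expect_equal(symmetry_index(0.4, 0.4), 1)
  expect_equal(symmetry_index(0.6, 0), 0)
  expect_equal(symmetry_index(0.6, 0.4), 1 - 0.2 / 0.6, tolerance = 1e-12)
  expect_true(is.na(symmetry_index(0, 0)))
  expect_error(symmetry_index(-1, 2), "non-negative")
  withr::with_seed(22, {
    r <- runif(1000, 0, 5)
    l <- runif(1000, 0, 5)
    si <- symmetry_index(r, l)
    expect_equal(si, 1 - abs(r - l) / pmax(r, l), tolerance = 1e-12)
    expect_true(all(si >= 0 & si <= 1))
  })
})

test_that("the feature roster is frozen at 50 with category counts 2/24/18/6", {
  roster <- feature_roster()
  expect_equal(nrow(roster), 50)
  expect_equal(
    as.integer(table(roster$category)[c(
      "macro", "micro_temporal", "micro_spatial", "micro_spatiotemporal"
    )]),
    c(2L, 24L, 18L, 6L)
  )
  expect_false(any(duplicated(roster$feature)))
})

test_that("extraction yields the full roster on a synthetic recording", {
  sim <- generate_recording(noiseless_walk_params(), seed = 7)
  fv <- extract_features(lowpass_filter(sim$recording))
  expect_equal(nrow(fv), 50)
  expect_equal(
    as.integer(table(fv$category)[c(
      "macro", "micro_temporal", "micro_spatial", "micro_spatiotemporal"
    )]),
    c(2L, 24L, 18L, 6L)
  )
  expect_identical(fv$feature, feature_roster()$feature)
  # variabilities are non-negative, symmetry indices within [0, 1]
  v <- fv$value[grepl("_var$", fv$feature) & !fv$missing]
  expect_true(all(v >= 0))
  si <- fv$value[grepl("(sym|reg)_(me|med)$", fv$feature) & !fv$missing]
  expect_true(all(si >= 0 & si <= 1))
})

test_that("a symmetric noiseless walker scores symmetry and regularity ~ 1", {
  sim <- generate_recording(noiseless_walk_params(), seed = 8)
  fv <- extract_features(lowpass_filter(sim$recording))
  val <- function(f) fv$value[fv$feature == f]
  expect_lt(abs(val("step_time_sym_me") - 1), 0.02)
  expect_lt(abs(val("stride_time_reg_me") - 1), 0.02)
})

test_that("spatial features recover the simulator's configured geometry", {
  sim <- generate_recording(noiseless_walk_params(), seed = 9)
  fv <- extract_features(lowpass_filter(sim$recording))
  val <- function(f) fv$value[fv$feature == f]
  expect_lt(abs(val("step_length_me") - 40), 2) # cm
  expect_lt(abs(val("step_width_me") - 0.15), 0.02) # m
  expect_lt(abs(val("step_height_me") - 0.12), 0.02) # m
})

test_that("macro features recover simulator velocity and cadence", {
  p <- walker_params(
    cadence = 69, step_length_mean = 0.40, step_length_sd = 0,
    step_time_sd = 0, step_width_sd = 0, step_height_sd = 0, noise_sd = 0,
    path_length_m = 9.2 # ~20 s at 0.46 m/s
  )
  sim <- generate_recording(p, seed = 10)
  rec <- lowpass_filter(sim$recording)
  d <- foot_distance_signal(rec)
  ev <- detect_step_events(d, rec)
  mac <- macro_features(rec, ev)
  expect_lt(abs(mac$velocity - 46), 2)
  expect_lt(abs(mac$cadence - 69), 69 * 0.03)
})

test_that("var features equal the variability oracle on the audit series", {
  sim <- generate_recording(
    walker_params(step_length_sd = 0.03, step_time_sd = 0.04, noise_sd = 0.003),
    seed = 11
  )
  fv <- extract_features(lowpass_filter(sim$recording))
  series <- attr(fv, "series")
  for (stem in names(series)) {
    expected <- variability(series[[stem]])
    got <- fv$value[fv$feature == paste0(stem, "_var")]
    if (is.na(expected)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, expected, tolerance = 1e-9)
    }
  }
})

test_that("stride velocity is consistent with stride length over time", {
  sim <- generate_recording(noiseless_walk_params(), seed = 12)
  fv <- extract_features(lowpass_filter(sim$recording))
  val <- function(f) fv$value[fv$feature == f]
  ratio <- val("stride_velocity_me") / (val("stride_length_me") / val("stride_time_me"))
  expect_lt(abs(ratio - 1), 0.10)
})

test_that("injected right/left asymmetry lowers step-time symmetry monotonically", {
  sym_me <- vapply(c(1.0, 1.1, 1.2), function(a) {
    sim <- generate_recording(noiseless_walk_params(lr_asymmetry = a), seed = 13)
    fv <- extract_features(lowpass_filter(sim$recording))
    fv$value[fv$feature == "step_time_sym_me"]
  }, numeric(1))
  expect_true(all(diff(sym_me) < 0))
})

test_that("extraction demands a filtered recording", {
  sim <- generate_recording(noiseless_walk_params(), seed = 14)
  expect_error(extract_features(sim$recording), "filter")
})
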