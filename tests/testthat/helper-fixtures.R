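# Shared fixtures, all built in code at test time.

# A recording with prescribed foot trajectories (T x 3 matrices, columns
# x/y/z); every other joint sits at a plausible static offset unless a
# SpineBase trajectory is supplied.
rec_with_feet <- function(foot_left, foot_right, fs = 30, spine_base = NULL,
                          filtered = TRUE, path_type = "straight") {
  n <- nrow(foot_left)
  joints <- gaitmci::kinect_joints()
  X <- matrix(0, n, 25, dimnames = list(NULL, joints))
  Y <- matrix(1, n, 25, dimnames = list(NULL, joints))
  Z <- matrix(0, n, 25, dimnames = list(NULL, joints))
  fill <- function(j, m) {
    X[, j] <<- m[, 1]; Y[, j] <<- m[, 2]; Z[, j] <<- m[, 3]
  }
  fill("FootLeft", foot_left)
  fill("FootRight", foot_right)
  fill("AnkleLeft", foot_left + matrix(rep(c(0, 0.07, 0), each = n), n))
  fill("AnkleRight", foot_right + matrix(rep(c(0, 0.07, 0), each = n), n))
  sb <- spine_base %||% cbind(
    (foot_left[, 1] + foot_right[, 1]) / 2,
    0.95,
    (foot_left[, 3] + foot_right[, 3]) / 2
  )
  fill("SpineBase", sb)
  skeletal_recording(
    positions = list(x = X, y = Y, z = Z),
    sampling_rate = fs, filtered = filtered, path_type = path_type
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small valid 2-frame recording for I/O round trips.
tiny_recording <- function(n = 2, fs = 30, seed = 1) {
  joints <- gaitmci::kinect_joints()
  withr::with_seed(seed, {
    skeletal_recording(
      positions = list(
        x = matrix(rnorm(n * 25), n, 25, dimnames = list(NULL, joints)),
        y = matrix(rnorm(n * 25) + 1, n, 25, dimnames = list(NULL, joints)),
        z = matrix(rnorm(n * 25), n, 25, dimnames = list(NULL, joints))
      ),
      sampling_rate = fs
    )
  })
}

# Canonical noiseless straight walk used across event/feature tests.
noiseless_walk_params <- function(...) {
  defaults <- list(
    cadence = 100, step_length_mean = 0.40, step_length_sd = 0,
    step_time_sd = 0, stance_fraction = 0.60,
    step_width_mean = 0.15, step_width_sd = 0,
    step_height_mean = 0.12, step_height_sd = 0,
    lr_asymmetry = 1, noise_sd = 0,
    path = "straight", path_length_m = 10, sampling_rate = 30
  )
  do.call(walker_params, utils::modifyList(defaults, list(...)))
}

# Memoised simulated cohort feature tables (shared between the classifier
# tests and the acceptance suite so the expensive simulations run once).
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort_features <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- suppressWarnings(
      simulate_cohort_features(cohort_config(n_hc = 30, n_mci = 25), seed = seed)
    )
  }
  .cohort_cache[[key]]
}
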