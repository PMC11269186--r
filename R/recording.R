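#' Construct a skeletal walking recording
#'
#' A `skeletal_recording` holds one walking trial: timestamped 3-D positions
#' of the 25 Kinect-v2 joints in a world frame whose axes are x (lateral),
#' y (vertical, up) and z (direction of progression), all in metres.
#'
#' @param positions A `T x 25 x 3` numeric array (frames x joints x xyz) with
#'   joint dimnames, or a named list with `T x 25` matrices `x`, `y`, `z`
#'   whose columns are the 25 joint names.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param timestamps Optional vector of frame times in seconds, strictly
#'   increasing; defaults to a uniform grid at `sampling_rate`.
#' @param subject_id Opaque subject identifier.
#' @param group Group label: `"HC"`, `"MCI"` or `"unknown"`.
#' @param path_type Walking path: `"straight"` or `"oval"`.
#' @param filtered Whether the recording has already been low-pass filtered.
#'
#' @return An object of class `skeletal_recording`.
#' @seealso [read_recording()], [lowpass_filter()], [generate_recording()]
#' @export
skeletal_recording <- function(positions, sampling_rate, timestamps = NULL,
                               subject_id = "unknown", group = "unknown",
                               path_type = "straight", filtered = FALSE) {
  joints <- kinect_joints()
  if (is.array(positions) && length(dim(positions)) == 3L) {
    stopifnot(dim(positions)[2] == 25L, dim(positions)[3] == 3L)
    jn <- dimnames(positions)[[2]] %||% joints
    pos <- list(
      x = positions[, , 1, drop = FALSE][, , 1],
      y = positions[, , 2, drop = FALSE][, , 1],
      z = positions[, , 3, drop = FALSE][, , 1]
    )
    pos <- lapply(pos, function(m) {
      m <- matrix(m, ncol = 25L, dimnames = list(NULL, jn))
      m[, joints, drop = FALSE]
    })
  } else if (is.list(positions) && all(c("x", "y", "z") %in% names(positions))) {
    pos <- lapply(positions[c("x", "y", "z")], function(m) {
      m <- as.matrix(m)
      if (is.null(colnames(m))) colnames(m) <- joints
      assert_joint(colnames(m))
      if (ncol(m) != 25L) {
        abort(paste0(
          "Recording must contain all 25 joints; missing: ",
          paste(setdiff(joints, colnames(m)), collapse = ", ")
        ))
      }
      m[, joints, drop = FALSE]
    })
  } else {
    abort("`positions` must be a T x 25 x 3 array or a list of x/y/z matrices.")
  }

  n <- nrow(pos$x)
  if (is.null(timestamps)) {
    timestamps <- seq(0, by = 1 / sampling_rate, length.out = n)
  }
  rec <- structure(
    list(
      subject_id = subject_id,
      group = match.arg(group, c("HC", "MCI", "unknown")),
      path_type = match.arg(path_type, c("straight", "oval")),
      sampling_rate = as.numeric(sampling_rate),
      timestamps = as.numeric(timestamps),
      x = pos$x, y = pos$y, z = pos$z,
      filtered = isTRUE(filtered)
    ),
    class = "skeletal_recording"
  )
  validate_recording(rec)
  rec
}

validate_recording <- function(rec, require_duration = FALSE) {
  if (!inherits(rec, "skeletal_recording")) {
    abort("Expected a `skeletal_recording` object.")
  }
  n <- length(rec$timestamps)
  if (n == 0L) abort("Recording has no frames (T = 0).")
  if (nrow(rec$x) != n || nrow(rec$y) != n || nrow(rec$z) != n) {
    abort("Position matrices and timestamps disagree in length.")
  }
  if (rec$sampling_rate <= 0) abort("sampling_rate must be > 0.")
  if (n > 1L && any(diff(rec$timestamps) <= 0)) {
    bad <- which(diff(rec$timestamps) <= 0)[1] + 1L
    abort(paste0("Timestamps must be strictly increasing (violated at frame ", bad, ")."))
  }
  if (!all(is.finite(rec$x)) || !all(is.finite(rec$y)) || !all(is.finite(rec$z))) {
    abort("All joint coordinates must be finite.")
  }
  if (require_duration && n < 2 * rec$sampling_rate) {
    abort("Recording must span at least 2 seconds for gait analysis.")
  }
  invisible(rec)
}

n_frames <- function(rec) length(rec$timestamps)

# T x 3 matrix of one joint's trajectory.
joint_xyz <- function(rec, joint) {
  assert_joint(joint)
  cbind(x = rec$x[, joint], y = rec$y[, joint], z = rec$z[, joint])
}

#' @export
print.skeletal_recording <- function(x, ...) {
  cat(sprintf(
    "<skeletal_recording> subject %s (%s, %s path)\n  %d frames @ %.1f Hz (%.1f s)%s\n",
    x$subject_id, x$group, x$path_type, n_frames(x), x$sampling_rate,
    diff(range(x$timestamps)), if (x$filtered) ", low-pass filtered" else ""
  ))
  invisible(x)
}

#' Convert a recording to a long tibble
#'
#' @param x A [skeletal_recording()].
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `joint`, `x_m`, `y_m`, `z_m`,
#'   one row per joint per frame.
#' @export
as_tibble.skeletal_recording <- function(x, ...) {
  joints <- kinect_joints()
  tibble(
    time_s = rep(x$timestamps, times = 25L),
    joint = rep(joints, each = n_frames(x)),
    x_m = as.vector(x$x),
    y_m = as.vector(x$y),
    z_m = as.vector(x$z)
  ) |>
    arrange(.data$time_s, match(.data$joint, joints))
}

#' Resample a recording onto a uniform time grid
#'
#' Real depth-camera streams can drop frames; downstream filtering assumes a
#' uniform grid. Linear interpolation at the recording's nominal sampling
#' rate; a warning is raised when the largest timestamp gap exceeds
#' `2 / sampling_rate`.
#'
#' @param rec A [skeletal_recording()].
#' @return A `skeletal_recording` with uniform timestamps.
#' @export
resample_uniform <- function(rec) {
  validate_recording(rec)
  ts <- rec$timestamps
  dt <- 1 / rec$sampling_rate
  if (length(ts) > 1L && max(diff(ts)) > 2 * dt) {
    warn(sprintf(
      "Largest timestamp gap (%.3f s) exceeds 2 frames; interpolation may mask lost tracking.",
      max(diff(ts))
    ))
  }
  grid <- seq(ts[1], ts[length(ts)], by = dt)
  interp <- function(m) {
    apply(m, 2, function(col) approx(ts, col, xout = grid)$y)
  }
  out <- rec
  out$timestamps <- grid
  out$x <- interp(rec$x)
  out$y <- interp(rec$y)
  out$z <- interp(rec$z)
  out
}

is_uniform <- function(rec, tol = 1e-6) {
  d <- diff(rec$timestamps)
  length(d) == 0L || (max(d) - min(d)) < tol
}
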