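#' Inter-foot distance signal
#'
#' Per-frame Euclidean separation of the two foot joints in the horizontal
#' (x, z) plane. Peaks of this signal mark step events; valleys mark the
#' feet passing each other around double support. The horizontal plane is
#' used by default so vertical foot clearance does not contaminate step
#' length; set `plane = "xyz"` for the full 3-D distance.
#'
#' @param rec A filtered [skeletal_recording()].
#' @param joint_pair Two joint names, default `c("FootLeft", "FootRight")`;
#'   ankles may track more reliably on real depth-camera data.
#' @param plane `"xz"` (horizontal, default) or `"xyz"`.
#' @return A tibble with columns `time_s` and `distance_m`, carrying the
#'   source joints as an attribute.
#' @export
foot_distance_signal <- function(rec, joint_pair = c("FootLeft", "FootRight"),
                                 plane = c("xz", "xyz")) {
  validate_recording(rec, require_duration = TRUE)
  plane <- match.arg(plane)
  assert_joint(joint_pair)
  a <- joint_xyz(rec, joint_pair[1])
  b <- joint_xyz(rec, joint_pair[2])
  d2 <- (a[, "x"] - b[, "x"])^2 + (a[, "z"] - b[, "z"])^2
  if (plane == "xyz") d2 <- d2 + (a[, "y"] - b[, "y"])^2
  out <- tibble(time_s = rec$timestamps, distance_m = sqrt(d2))
  attr(out, "source_joints") <- joint_pair
  out
}

# Local maxima with prominences. Returns tibble(index, value, prominence),
# prominence-filtered and thinned to a minimum index spacing (highest first).
find_peaks <- function(x, min_prominence = 0, min_spacing = 1L) {
  n <- length(x)
  if (n < 3L) {
    return(tibble(index = integer(), value = numeric(), prominence = numeric()))
  }
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  # collapse plateau runs to their midpoint
  if (length(cand) > 1L) {
    keep <- c(TRUE, diff(cand) > 1L | x[cand[-1]] != x[cand[-length(cand)]])
    cand <- cand[keep]
  }
  if (length(cand) == 0L) {
    return(tibble(index = integer(), value = numeric(), prominence = numeric()))
  }
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lo_l <- h
    j <- i
    while (j > 1L && x[j] <= h) {
      j <- j - 1L
      lo_l <- min(lo_l, x[j])
      if (x[j] > h) break
    }
    lo_r <- h
    j <- i
    while (j < n && x[j] <= h) {
      j <- j + 1L
      lo_r <- min(lo_r, x[j])
      if (x[j] > h) break
    }
    h - max(lo_l, lo_r)
  }, numeric(1))
  ok <- prom >= min_prominence
  cand <- cand[ok]
  prom <- prom[ok]
  if (length(cand) > 1L && min_spacing > 1L) {
    ord <- order(x[cand], decreasing = TRUE)
    sel <- logical(length(cand))
    taken <- integer(0)
    for (k in ord) {
      if (all(abs(cand[k] - taken) >= min_spacing)) {
        sel[k] <- TRUE
        taken <- c(taken, cand[k])
      }
    }
    cand <- cand[sel]
    prom <- prom[sel]
  }
  o <- order(cand)
  tibble(index = cand[o], value = x[cand[o]], prominence = prom[o])
}

# Unit heading of progression per frame, from the SpineBase horizontal
# velocity smoothed over `smooth_s` seconds. Needed on oval paths where the
# direction of progression rotates continuously.
estimate_heading <- function(rec, smooth_s = 0.5) {
  sb <- joint_xyz(rec, "SpineBase")
  w <- round(smooth_s * rec$sampling_rate)
  vx <- moving_average(central_diff(sb[, "x"], rec$timestamps), w)
  vz <- moving_average(central_diff(sb[, "z"], rec$timestamps), w)
  sp <- sqrt(vx^2 + vz^2)
  # where the pelvis is momentarily still, carry the last reliable heading
  ok <- sp > 1e-6
  if (!any(ok)) {
    return(cbind(dx = rep(0, nrow(sb)), dz = rep(1, nrow(sb))))
  }
  hx <- vx / pmax(sp, 1e-12)
  hz <- vz / pmax(sp, 1e-12)
  first_ok <- which(ok)[1]
  for (i in seq_along(hx)) {
    if (!ok[i]) {
      if (i < first_ok) {
        hx[i] <- hx[first_ok]; hz[i] <- hz[first_ok]
      } else if (i > 1L) {
        hx[i] <- hx[i - 1L]; hz[i] <- hz[i - 1L]
      }
    }
  }
  cbind(dx = hx, dz = hz)
}

#' Detect step events from the inter-foot distance signal
#'
#' Each peak of the distance signal marks a step: the moment the leading
#' foot is planted furthest ahead of the trailing foot. The leading foot is
#' the one further along the local heading at the peak; step length is the
#' along-heading component of the inter-foot vector (its perpendicular
#' component is the step width). Partial steps before the first valley and
#' after the last valley are discarded.
#'
#' @param d A [foot_distance_signal()] tibble.
#' @param rec The recording the signal came from.
#' @param min_peak_distance_s Minimum spacing of step peaks in seconds
#'   (default 0.3 s, i.e. a cap of ~200 steps/min).
#' @param min_prominence_m Minimum peak prominence in metres (default 0.05).
#' @return A tibble of step events: `index`, `time`, `leading_foot`,
#'   `step_length` (m, along-heading), `step_width` (m, lateral),
#'   `peak_distance` (m, raw signal value), `frame`.
#' @export
detect_step_events <- function(d, rec, min_peak_distance_s = 0.3,
                               min_prominence_m = 0.05) {
  stopifnot(is.data.frame(d), all(c("time_s", "distance_m") %in% names(d)))
  validate_recording(rec, require_duration = TRUE)
  joint_pair <- attr(d, "source_joints") %||% c("FootLeft", "FootRight")
  fs <- rec$sampling_rate
  spacing <- max(1L, round(min_peak_distance_s * fs))
  pk <- find_peaks(d$distance_m, min_prominence = min_prominence_m,
                   min_spacing = spacing)
  vl <- find_peaks(-d$distance_m, min_prominence = min_prominence_m,
                   min_spacing = spacing)
  if (nrow(pk) >= 1L && nrow(vl) >= 2L) {
    pk <- pk[pk$index > min(vl$index) & pk$index < max(vl$index), , drop = FALSE]
  }
  if (nrow(pk) < 4L) {
    abort("Insufficient gait: fewer than 4 step events detected.")
  }

  heading <- estimate_heading(rec)
  a <- joint_xyz(rec, joint_pair[1]) # left by convention
  b <- joint_xyz(rec, joint_pair[2]) # right
  idx <- pk$index
  h <- heading[idx, , drop = FALSE]
  # displacement of each foot along heading, relative to their midpoint
  dxv <- a[idx, "x"] - b[idx, "x"]
  dzv <- a[idx, "z"] - b[idx, "z"]
  along_diff <- dxv * h[, "dx"] + dzv * h[, "dz"] # left minus right
  lateral <- abs(dxv * h[, "dz"] - dzv * h[, "dx"])
  lead <- ifelse(along_diff > 0, "left",
                 ifelse(along_diff < 0, "right", NA_character_))
  # ties: alternate from the previous event
  for (k in seq_along(lead)) {
    if (is.na(lead[k])) {
      lead[k] <- if (k == 1L) "left" else setdiff(c("left", "right"), lead[k - 1L])
    }
  }
  ev <- tibble(
    index = seq_along(idx),
    time = d$time_s[idx],
    leading_foot = lead,
    step_length = abs(along_diff),
    step_width = lateral,
    peak_distance = pk$value,
    frame = idx
  )
  ev
}

#' Label stance and swing phases per foot
#'
#' A foot is in stance while its horizontal speed (central-difference
#' derivative of the filtered trajectory) stays below a stance threshold,
#' and in swing otherwise; label runs shorter than `min_phase_s` are merged
#' into their neighbours. Support labels follow from the two foot labels:
#' both in stance is double support, exactly one is single support of the
#' stance foot. Frames where both feet appear to swing (impossible in
#' walking) are reassigned to stance of the slower foot.
#'
#' By default the threshold adapts to each foot's swing speed:
#' `threshold_fraction` times the 95th percentile of that foot's horizontal
#' speed, floored at `min_threshold`. Low-pass filtering smears the
#' stance/swing transition, so a fixed low threshold systematically widens
#' swing for brisk gait; a speed-relative threshold keeps the boundary near
#' the true transition across gait speeds. Pass a number as
#' `speed_threshold` for a fixed absolute threshold instead.
#'
#' @param rec A filtered [skeletal_recording()].
#' @param speed_threshold Fixed stance speed threshold in m/s, or `NULL`
#'   (default) for the adaptive threshold.
#' @param min_phase_s Minimum phase duration in seconds (default 0.1).
#' @param joint_pair Foot joints to use.
#' @param threshold_fraction,min_threshold Adaptive-threshold tuning:
#'   fraction of the per-foot 95th-percentile speed (default 0.15) and the
#'   absolute floor in m/s (default 0.1, a post-filter jitter budget).
#' @return A tibble with columns `time_s`, `left`, `right` (each
#'   `"stance"`/`"swing"`) and `support` (`"double_support"`,
#'   `"single_support_left"`, `"single_support_right"`).
#' @export
label_phases <- function(rec, speed_threshold = NULL, min_phase_s = 0.1,
                         joint_pair = c("FootLeft", "FootRight"),
                         threshold_fraction = 0.15, min_threshold = 0.1) {
  validate_recording(rec, require_duration = TRUE)
  fs <- rec$sampling_rate
  min_len <- max(1L, round(min_phase_s * fs))
  foot_speed <- function(j) {
    p <- joint_xyz(rec, j)
    sqrt(central_diff(p[, "x"], rec$timestamps)^2 +
           central_diff(p[, "z"], rec$timestamps)^2)
  }
  sp_l <- foot_speed(joint_pair[1])
  sp_r <- foot_speed(joint_pair[2])
  thr <- function(sp) {
    if (!is.null(speed_threshold)) {
      return(speed_threshold)
    }
    max(min_threshold, threshold_fraction * quantile(sp, 0.95, names = FALSE))
  }
  lab_l <- debounce_runs(sp_l < thr(sp_l), min_len)
  lab_r <- debounce_runs(sp_r < thr(sp_r), min_len)
  # no flight phase in walking: both-swing frames go to the slower foot
  flight <- !lab_l & !lab_r
  if (any(flight)) {
    to_left <- flight & (sp_l <= sp_r)
    lab_l[to_left] <- TRUE
    lab_r[flight & !to_left] <- TRUE
  }
  if (all(lab_l) && all(lab_r)) {
    sb <- joint_xyz(rec, "SpineBase")
    moved <- sqrt(diff(range(sb[, "x"]))^2 + diff(range(sb[, "z"]))^2)
    if (moved > 1) {
      warn("Whole trial labelled as one phase despite subject movement; subphase features will be missing.")
    }
  }
  tibble(
    time_s = rec$timestamps,
    left = ifelse(lab_l, "stance", "swing"),
    right = ifelse(lab_r, "stance", "swing"),
    support = dplyr::case_when(
      lab_l & lab_r ~ "double_support",
      lab_l & !lab_r ~ "single_support_left",
      !lab_l & lab_r ~ "single_support_right",
      TRUE ~ "flight_artifact"
    )
  )
}

# Merge runs shorter than min_len into their neighbours, shortest first.
debounce_runs <- function(lab, min_len) {
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L) {
      return(lab)
    }
    short <- which(r$lengths < min_len)
    if (length(short) == 0L) {
      return(lab)
    }
    k <- short[which.min(r$lengths[short])]
    r$values[k] <- !r$values[k]
    lab <- inverse.rle(r)
    lab <- inverse.rle(rle(lab)) # re-merge equal neighbours on next pass
  }
}

#' Segment gait cycles from step events and phase labels
#'
#' One gait cycle (stride) spans two successive steps: from a step event of
#' one foot to the next event of the same foot. Stride time is the interval
#' between the two same-foot events, stride length the sum of the two
#' constituent step lengths; stance/swing and support durations are
#' integrated from the phase labels inside the cycle window. Double- and
#' single-support times are mean bout durations within the window.
#'
#' @param events A [detect_step_events()] tibble.
#' @param phases A [label_phases()] tibble.
#' @param d The [foot_distance_signal()] the events came from (used for the
#'   sampling grid).
#' @return A tibble of cycles: `foot`, `start_time`, `end_time`,
#'   `stride_time`, `stride_length`, `stance_time`, `swing_time`,
#'   `double_support_time`, `single_support_time`.
#' @export
segment_gait_cycles <- function(events, phases, d) {
  if (nrow(events) < 4L) {
    abort("Insufficient gait: at least 4 step events are needed to form strides.")
  }
  dt <- median(diff(phases$time_s))
  cycles <- vector("list", nrow(events) - 2L)
  for (k in seq_len(nrow(events) - 2L)) {
    e0 <- events[k, ]
    e2 <- events[k + 2L, ]
    if (e0$leading_foot != e2$leading_foot ||
        events$leading_foot[k + 1L] == e0$leading_foot) {
      warn(sprintf(
        "Left/right alternation violated around t = %.2f s; cycle skipped.", e0$time
      ))
      next
    }
    win <- phases$time_s >= e0$time & phases$time_s < e2$time
    if (!any(win)) next
    foot_lab <- if (e0$leading_foot == "left") phases$left[win] else phases$right[win]
    stance_time <- sum(foot_lab == "stance") * dt
    stride_time <- e2$time - e0$time
    ds <- mean_bout_duration(phases$support[win] == "double_support", dt)
    own_ss <- paste0("single_support_", e0$leading_foot)
    ss <- mean_bout_duration(phases$support[win] == own_ss, dt)
    cycles[[k]] <- tibble(
      foot = e0$leading_foot,
      start_time = e0$time,
      end_time = e2$time,
      stride_time = stride_time,
      stride_length = events$step_length[k + 1L] + events$step_length[k + 2L],
      stance_time = stance_time,
      swing_time = stride_time - stance_time,
      double_support_time = ds,
      single_support_time = ss
    )
  }
  out <- list_rbind(cycles[!vapply(cycles, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    abort("No valid gait cycles could be segmented.")
  }
  out
}

mean_bout_duration <- function(flag, dt) {
  r <- rle(flag)
  lens <- r$lengths[r$values]
  if (length(lens) == 0L) {
    return(NA_real_)
  }
  mean(lens) * dt
}
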