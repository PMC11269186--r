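#' Canonical 50-feature gait roster
#'
#' The frozen roster of gait features extracted from every walking trial:
#' 2 macro features (whole-trial velocity and cadence), 24 micro temporal,
#' 18 micro spatial and 6 micro spatiotemporal features. Per-step and
#' per-cycle quantities are aggregated as mean (`_me`), variability (`_var`,
#' 100 * SD / mean, in percent) and median (`_med`); symmetry (`_sym`) and
#' regularity (`_reg`) indices compare right and left feet.
#'
#' @return A tibble with columns `feature`, `unit`, `category`.
#' @export
feature_roster <- function() {
  agg <- function(stem, unit, category, index = FALSE) {
    tibble(
      feature = paste0(stem, c("_me", "_var", "_med")),
      unit = c(if (index) "index" else unit, "%", if (index) "index" else unit),
      category = category
    )
  }
  dplyr::bind_rows(
    tibble(feature = c("velocity", "cadence"),
           unit = c("cm/s", "steps/min"), category = "macro"),
    agg("stance_time", "s", "micro_temporal"),
    agg("swing_time", "s", "micro_temporal"),
    agg("double_support_time", "s", "micro_temporal"),
    agg("single_support_time", "s", "micro_temporal"),
    agg("step_time", "s", "micro_temporal"),
    agg("step_time_sym", "s", "micro_temporal", index = TRUE),
    agg("stride_time", "s", "micro_temporal"),
    agg("stride_time_reg", "s", "micro_temporal", index = TRUE),
    agg("step_length", "cm", "micro_spatial"),
    agg("step_length_sym", "cm", "micro_spatial", index = TRUE),
    agg("step_width", "m", "micro_spatial"),
    agg("step_height", "m", "micro_spatial"),
    agg("stride_length", "cm", "micro_spatial"),
    agg("stride_length_reg", "cm", "micro_spatial", index = TRUE),
    agg("step_velocity", "cm/s", "micro_spatiotemporal"),
    agg("stride_velocity", "cm/s", "micro_spatiotemporal")
  )
}

#' Variability of a per-step or per-cycle series
#'
#' `100 * sd(x) / mean(x)` (coefficient of variation, percent), with the
#' sample (n - 1) standard deviation.
#'
#' @param values Numeric vector of at least 2 values.
#' @return Percent variability, or `NA` when the mean is within 1e-12 of
#'   zero (undefined) or fewer than 2 values are available.
#' @export
#' @examples
#' variability(c(1, 2, 3)) # 50
variability <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    return(NA_real_)
  }
  m <- mean(values)
  if (abs(m) < 1e-12) {
    return(NA_real_)
  }
  100 * sd(values) / m
}

#' Symmetry / regularity index of right vs left gait quantities
#'
#' `1 - |x_right - x_left| / max(x_right, x_left)`, ranging from 0 (total
#' asymmetry) to 1 (perfect symmetry). Vectorised.
#'
#' @param x_right,x_left Non-negative quantities for the right and left foot.
#' @return Values in `[0, 1]`; `NA` where both inputs are zero.
#' @export
#' @examples
#' symmetry_index(0.6, 0.4) # 0.667
symmetry_index <- function(x_right, x_left) {
  if (any(c(x_right, x_left) < 0, na.rm = TRUE)) {
    abort("symmetry_index() requires non-negative inputs.")
  }
  mx <- pmax(x_right, x_left)
  out <- 1 - abs(x_right - x_left) / mx
  out[mx == 0] <- NA_real_
  out
}

#' Whole-trial macro gait features
#'
#' Average velocity and cadence. On a straight path, velocity is the
#' start-to-end displacement of the foot joint (the larger of the two feet,
#' i.e. the one that completed the course) divided by the trial duration;
#' on an oval path the start and end points nearly coincide, so the
#' horizontal arc length of the SpineBase trajectory is used instead.
#' Cadence is derived from the interior step events:
#' `60 * (n_events - 1) / (time of last - time of first)`.
#'
#' @param rec A filtered [skeletal_recording()].
#' @param events A [detect_step_events()] tibble with at least 4 events.
#' @return A tibble with `velocity` (cm/s) and `cadence` (steps/min).
#' @export
macro_features <- function(rec, events) {
  validate_recording(rec, require_duration = TRUE)
  if (nrow(events) < 4L) abort("Insufficient gait: fewer than 4 step events.")
  duration <- rec$timestamps[n_frames(rec)] - rec$timestamps[1]
  if (duration <= 0) abort("Trial has zero duration.")
  if (rec$path_type == "straight") {
    foot_disp <- function(j) {
      p <- joint_xyz(rec, j)
      sqrt((p[nrow(p), "x"] - p[1, "x"])^2 + (p[nrow(p), "z"] - p[1, "z"])^2)
    }
    # the foot that stepped last has covered the full course
    disp <- max(foot_disp("FootLeft"), foot_disp("FootRight"))
  } else {
    sb <- joint_xyz(rec, "SpineBase")
    disp <- sum(sqrt(diff(sb[, "x"])^2 + diff(sb[, "z"])^2))
  }
  cadence <- 60 * (nrow(events) - 1L) /
    (events$time[nrow(events)] - events$time[1])
  tibble(velocity = 100 * disp / duration, cadence = cadence)
}

# Per-step step-height series: peak swing clearance of the stepping foot
# above its preceding stance baseline.
step_height_series <- function(rec, events, phases) {
  vapply(seq_len(nrow(events)), function(k) {
    foot <- events$leading_foot[k]
    y <- if (foot == "left") rec$y[, "FootLeft"] else rec$y[, "FootRight"]
    lab <- if (foot == "left") phases$left else phases$right
    t0 <- if (k == 1L) rec$timestamps[1] else events$time[k - 1L]
    win <- which(phases$time_s > t0 & phases$time_s <= events$time[k])
    sw <- win[lab[win] == "swing"]
    if (length(sw) == 0L) {
      return(NA_real_)
    }
    # baseline: contiguous stance run just before swing onset
    i <- sw[1] - 1L
    base_idx <- integer(0)
    while (i >= 1L && lab[i] == "stance" && length(base_idx) < 2L * rec$sampling_rate) {
      base_idx <- c(base_idx, i)
      i <- i - 1L
    }
    if (length(base_idx) == 0L) {
      return(NA_real_)
    }
    max(y[sw]) - mean(y[base_idx])
  }, numeric(1))
}

#' Extract the 50-feature gait vector from one recording
#'
#' Runs event detection, phase labelling and cycle segmentation on a
#' filtered recording, builds the per-step and per-cycle series, and
#' aggregates them into the canonical 50-feature roster (see
#' [feature_roster()]). Values are reported in presentation units
#' (velocities cm/s, step/stride lengths cm, widths/heights m, times s,
#' variabilities %, symmetry indices unitless). Features whose series
#' cannot be computed are kept as explicit missing values with a reason;
#' the whole extraction fails only when too few steps are detected.
#'
#' The per-step and per-cycle series used for aggregation are attached as
#' `attr(result, "series")` for audit, along with the detected events and
#' cycles (`attr(result, "events")`, `attr(result, "cycles")`).
#'
#' @param rec A filtered [skeletal_recording()].
#' @param min_peak_distance_s,min_prominence_m Passed to
#'   [detect_step_events()].
#' @param ... Passed to [label_phases()].
#' @return A tibble with 50 rows: `feature`, `value`, `unit`, `category`,
#'   `missing`, `reason`.
#' @export
extract_features <- function(rec, min_peak_distance_s = 0.3,
                             min_prominence_m = 0.05, ...) {
  validate_recording(rec, require_duration = TRUE)
  if (!isTRUE(rec$filtered)) {
    abort("extract_features() expects a low-pass filtered recording; call lowpass_filter() first.")
  }
  d <- foot_distance_signal(rec)
  events <- detect_step_events(d, rec,
                               min_peak_distance_s = min_peak_distance_s,
                               min_prominence_m = min_prominence_m)
  phases <- label_phases(rec, ...)
  cycles <- segment_gait_cycles(events, phases, d)
  macro <- macro_features(rec, events)
  ne <- nrow(events)

  step_time <- diff(events$time) # step k+1 relative to k
  step_time_foot <- events$leading_foot[-1]
  step_len <- events$step_length
  step_vel <- step_len[-1] / step_time

  # symmetry: each adjacent pair of opposite-foot steps yields one SI value
  pair_si <- function(x, foot) {
    n <- length(x)
    if (n < 2L) {
      return(numeric(0))
    }
    keep <- foot[-n] != foot[-1]
    r <- ifelse(foot[-n] == "right", x[-n], x[-1])
    l <- ifelse(foot[-n] == "right", x[-1], x[-n])
    symmetry_index(r[keep], l[keep])
  }
  sym_time <- pair_si(step_time, step_time_foot)
  sym_len <- pair_si(step_len, events$leading_foot)

  # regularity: each right-foot stride vs its nearest-in-time left-foot stride
  reg_series <- function(x) {
    ri <- which(cycles$foot == "right")
    li <- which(cycles$foot == "left")
    if (length(ri) == 0L || length(li) == 0L) {
      return(numeric(0))
    }
    nearest <- li[vapply(
      cycles$start_time[ri],
      function(t) which.min(abs(cycles$start_time[li] - t)), integer(1)
    )]
    symmetry_index(x[ri], x[nearest])
  }
  reg_time <- reg_series(cycles$stride_time)
  reg_len <- reg_series(cycles$stride_length)

  series <- list(
    stance_time = cycles$stance_time,
    swing_time = cycles$swing_time,
    double_support_time = cycles$double_support_time[!is.na(cycles$double_support_time)],
    single_support_time = cycles$single_support_time[!is.na(cycles$single_support_time)],
    step_time = step_time,
    step_time_sym = sym_time,
    stride_time = cycles$stride_time,
    stride_time_reg = reg_time,
    step_length = step_len * 100, # cm
    step_length_sym = sym_len,
    step_width = events$step_width,
    step_height = step_height_series(rec, events, phases),
    stride_length = cycles$stride_length * 100, # cm
    stride_length_reg = reg_len,
    step_velocity = step_vel * 100, # cm/s
    stride_velocity = 100 * cycles$stride_length / cycles$stride_time
  )
  series$step_height <- series$step_height[!is.na(series$step_height)]

  roster <- feature_roster()
  values <- numeric(nrow(roster))
  reasons <- rep(NA_character_, nrow(roster))
  for (i in seq_len(nrow(roster))) {
    f <- roster$feature[i]
    if (f %in% c("velocity", "cadence")) {
      values[i] <- macro[[f]]
      next
    }
    stem <- sub("_(me|var|med)$", "", f)
    agg <- sub("^.*_(me|var|med)$", "\\1", f)
    x <- series[[stem]]
    if (length(x) == 0L) {
      values[i] <- NA_real_
      reasons[i] <- paste0("no ", gsub("_", " ", stem), " values available")
      next
    }
    values[i] <- switch(agg,
      me = mean(x),
      med = median(x),
      var = variability(x)
    )
    if (is.na(values[i]) && agg == "var") {
      reasons[i] <- "variability undefined (mean ~ 0 or < 2 values)"
    }
  }
  out <- tibble(
    feature = roster$feature,
    value = values,
    unit = roster$unit,
    category = roster$category,
    missing = is.na(values),
    reason = reasons
  )
  attr(out, "series") <- series
  attr(out, "events") <- events
  attr(out, "cycles") <- cycles
  out
}

#' Extract features for every trial in a manifest
#'
#' Reads each recording listed in a cohort manifest, applies the low-pass
#' filter and [extract_features()], and returns a wide cohort table: one
#' row per subject x trial, 50 feature columns plus the manifest metadata.
#'
#' @param manifest A manifest tibble from [read_manifest()] or
#'   [generate_cohort()].
#' @param filter_order,cutoff_hz Passed to [lowpass_filter()].
#' @param ... Passed to [extract_features()].
#' @return A tibble with metadata and 50 feature columns.
#' @export
extract_cohort_features <- function(manifest, filter_order = 6L,
                                    cutoff_hz = 3.0, ...) {
  rows <- map(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    rec <- read_recording(
      m$recording_path,
      subject_id = m$subject_id, group = m$group, path_type = m$path_type
    )
    fv <- extract_features(
      lowpass_filter(rec, order = filter_order, cutoff_hz = cutoff_hz), ...
    )
    wide <- tidyr::pivot_wider(fv[, c("feature", "value")],
                               names_from = "feature", values_from = "value")
    dplyr::bind_cols(m[, setdiff(names(m), "recording_path")], wide)
  })
  list_rbind(rows)
}
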