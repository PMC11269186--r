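#' Parameters of the synthetic walker
#'
#' Describes one subject's gait for the event-driven walking simulator.
#' Foot placements are spaced along the walking path with alternating
#' left/right lateral offsets; step durations and lengths are sampled per
#' step; each foot is perfectly stationary during its stance interval and
#' follows a smooth forward interpolation with sinusoidal vertical clearance
#' during swing. Defaults describe a typical older-adult straight 10-m walk.
#'
#' @param cadence Steps per minute.
#' @param step_length_mean,step_length_sd Per-step arc length in metres
#'   (mean, within-subject SD).
#' @param step_time_sd Within-subject SD of the step duration (s).
#' @param stance_fraction Fraction of the stride spent in stance, in
#'   (0.5, 0.8); double support occupies `2 * stance_fraction - 1` of the
#'   stride by construction.
#' @param step_width_mean,step_width_sd Lateral inter-foot separation (m).
#' @param step_height_mean,step_height_sd Peak vertical swing-foot clearance (m).
#' @param lr_asymmetry Multiplicative factor applied to right-side step time
#'   and length (1 = symmetric gait).
#' @param noise_sd Additive Gaussian positional noise per joint coordinate
#'   (m), applied before any filtering.
#' @param path `"straight"` or `"oval"`.
#' @param path_length_m Straight-path length (m).
#' @param oval_straight_m,oval_radius_m,laps Oval geometry: two straight
#'   segments of this length joined by semicircles of this radius, walked
#'   for `laps` laps.
#' @param sampling_rate Sampling rate in Hz.
#' @param lead_in_s,lead_out_s Standing time before the first and after the
#'   last step (s).
#'
#' @return A list of class `walker_params`.
#' @export
walker_params <- function(cadence = 68,
                          step_length_mean = 0.36, step_length_sd = 0.03,
                          step_time_sd = 0.03,
                          stance_fraction = 0.60,
                          step_width_mean = 0.12, step_width_sd = 0.02,
                          step_height_mean = 0.11, step_height_sd = 0.015,
                          lr_asymmetry = 1.0,
                          noise_sd = 0.003,
                          path = c("straight", "oval"),
                          path_length_m = 10,
                          oval_straight_m = 3, oval_radius_m = 1, laps = 1,
                          sampling_rate = 30,
                          lead_in_s = 0.25, lead_out_s = 0.25) {
  path <- match.arg(path)
  p <- as.list(environment())
  stopifnot(
    cadence > 0, step_length_mean > 0, step_length_sd >= 0,
    step_time_sd >= 0, stance_fraction > 0.5, stance_fraction < 0.8,
    step_width_mean > 0, step_height_mean > 0, lr_asymmetry > 0,
    noise_sd >= 0, sampling_rate > 0
  )
  structure(p, class = "walker_params")
}

# Path geometry: arc-length parameterisation of the walking course.
# Returns point(s) and heading(s) as n x 2 matrices of (x, z).
make_path <- function(params) {
  if (params$path == "straight") {
    list(
      total = params$path_length_m,
      point = function(s) cbind(x = rep(0, length(s)), z = s),
      heading = function(s) cbind(dx = rep(0, length(s)), dz = rep(1, length(s)))
    )
  } else {
    A <- params$oval_straight_m
    r <- params$oval_radius_m
    per <- 2 * A + 2 * pi * r
    point1 <- function(u) {
      x <- numeric(length(u))
      z <- numeric(length(u))
      i1 <- u < A
      x[i1] <- 0; z[i1] <- u[i1]
      i2 <- u >= A & u < A + pi * r
      phi <- (u[i2] - A) / r
      x[i2] <- r - r * cos(phi); z[i2] <- A + r * sin(phi)
      i3 <- u >= A + pi * r & u < 2 * A + pi * r
      x[i3] <- 2 * r; z[i3] <- A - (u[i3] - A - pi * r)
      i4 <- u >= 2 * A + pi * r
      phi <- (u[i4] - 2 * A - pi * r) / r
      x[i4] <- r + r * cos(phi); z[i4] <- -r * sin(phi)
      cbind(x = x, z = z)
    }
    heading1 <- function(u) {
      dx <- numeric(length(u))
      dz <- numeric(length(u))
      i1 <- u < A
      dx[i1] <- 0; dz[i1] <- 1
      i2 <- u >= A & u < A + pi * r
      phi <- (u[i2] - A) / r
      dx[i2] <- sin(phi); dz[i2] <- cos(phi)
      i3 <- u >= A + pi * r & u < 2 * A + pi * r
      dx[i3] <- 0; dz[i3] <- -1
      i4 <- u >= 2 * A + pi * r
      phi <- (u[i4] - 2 * A - pi * r) / r
      dx[i4] <- -sin(phi); dz[i4] <- -cos(phi)
      cbind(dx = dx, dz = dz)
    }
    list(
      total = params$laps * per,
      point = function(s) point1(s %% per),
      heading = function(s) heading1(s %% per)
    )
  }
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

truncnorm1 <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  tries <- 0L
  while (length(bad) > 0L && tries < 50L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
    tries <- tries + 1L
  }
  x[x < lower] <- lower
  x
}

#' Simulate one skeletal walking recording with ground truth
#'
#' Event-driven walking simulator: a step schedule (contact time, foot,
#' placement along the path) is drawn from [walker_params()], foot
#' trajectories are rendered frame by frame (stationary in stance, smooth
#' swing with sinusoidal clearance), the pelvis follows the path midline and
#' the remaining joints are rigid offsets from the pelvis frame with small
#' oscillations for visual plausibility only. Gaussian positional noise is
#' added last. The returned ground truth records the exact step schedule,
#' per-frame phase labels and realised parameter values, so downstream
#' detectors can be scored against it.
#'
#' @param params A [walker_params()].
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param subject_id,group Metadata stamped on the recording.
#' @return A list with elements `recording` (a [skeletal_recording()]) and
#'   `ground_truth` (step events, per-frame phases, realised parameters).
#' @export
#' @examples
#' sim <- generate_recording(walker_params(path_length_m = 6), seed = 42)
#' sim$recording
#' head(sim$ground_truth$events)
generate_recording <- function(params, seed, subject_id = "sim",
                               group = "unknown") {
  stopifnot(inherits(params, "walker_params"))
  path <- make_path(params)
  mean_step_time <- 60 / params$cadence

  # -- step schedule ---------------------------------------------------------
  n_guess <- ceiling(path$total / max(params$step_length_mean * 0.5, 0.05)) + 4L
  sched <- with_seed(derive_seed(seed, 1L), {
    foot <- rep(c("right", "left"), length.out = n_guess)
    asym <- ifelse(foot == "right", params$lr_asymmetry, 1)
    len <- truncnorm1(n_guess, params$step_length_mean * asym,
                      params$step_length_sd, lower = 0.05)
    dur <- truncnorm1(n_guess, mean_step_time * asym,
                      params$step_time_sd, lower = 0.15)
    wid <- truncnorm1(n_guess, params$step_width_mean,
                      params$step_width_sd, lower = 0.02)
    hgt <- truncnorm1(n_guess, params$step_height_mean,
                      params$step_height_sd, lower = 0.01)
    tibble(foot = foot, step_length = len, step_time = dur,
           width = wid, height = hgt)
  })
  sched$s <- cumsum(sched$step_length)
  keep <- sched$s <= path$total + params$step_length_mean
  sched <- sched[keep & cumsum(!keep) == 0, , drop = FALSE]
  sched <- sched[sched$s <= path$total | seq_len(nrow(sched)) == which.max(sched$s > path$total), , drop = FALSE]
  sched$s <- pmin(sched$s, path$total)
  n_steps <- nrow(sched)
  if (n_steps < 4L) {
    abort("Walking path is shorter than two strides; increase the path length.")
  }
  sched$index <- seq_len(n_steps)
  sched$t_contact <- params$lead_in_s + cumsum(sched$step_time)

  t_end <- sched$t_contact[n_steps] + params$lead_out_s
  dt <- 1 / params$sampling_rate
  t_grid <- seq(0, t_end, by = dt)
  nf <- length(t_grid)

  # -- per-foot placement lists (initial posture + steps) --------------------
  half_w0 <- params$step_width_mean / 2
  foot_ground_y <- 0.05
  render_foot <- function(side) {
    rows <- sched[sched$foot == side, , drop = FALSE]
    sign_lat <- if (side == "right") 1 else -1
    pl <- tibble(
      t = c(0, rows$t_contact),
      s = c(0, rows$s),
      lat = sign_lat * c(half_w0, rows$width / 2),
      height = c(0, rows$height)
    )
    np <- nrow(pl)
    sf <- rep(pl$s[np], nf)
    latf <- rep(pl$lat[np], nf)
    yf <- rep(foot_ground_y, nf)
    stance <- rep(TRUE, nf)
    for (i in seq_len(np - 1L)) {
      t0 <- pl$t[i]; t1 <- pl$t[i + 1L]
      swing_dur <- (1 - params$stance_fraction) * (t1 - t0)
      sw0 <- t1 - swing_dur
      hold <- t_grid >= t0 & t_grid < sw0
      sf[hold] <- pl$s[i]; latf[hold] <- pl$lat[i]
      sw <- t_grid >= sw0 & t_grid < t1
      if (any(sw)) {
        tau <- (t_grid[sw] - sw0) / swing_dur
        h <- smoothstep(tau)
        sf[sw] <- pl$s[i] + h * (pl$s[i + 1L] - pl$s[i])
        latf[sw] <- pl$lat[i] + h * (pl$lat[i + 1L] - pl$lat[i])
        yf[sw] <- foot_ground_y + pl$height[i + 1L] * sin(pi * tau)
        stance[sw] <- FALSE
      }
    }
    before <- t_grid < pl$t[1]
    sf[before] <- pl$s[1]; latf[before] <- pl$lat[1]
    pt <- path$point(sf)
    hd <- path$heading(sf)
    nrm <- cbind(hd[, 2], -hd[, 1]) # rightward normal in (x, z)
    list(
      xyz = cbind(
        x = pt[, 1] + latf * nrm[, 1],
        y = yf,
        z = pt[, 2] + latf * nrm[, 2]
      ),
      stance = stance
    )
  }
  left <- render_foot("left")
  right <- render_foot("right")

  # -- pelvis and decorative joints ------------------------------------------
  mid_knots_t <- c(0, sched$t_contact, t_end)
  mid_knots_s <- c(0, (sched$s + dplyr::lag(sched$s, default = 0)) / 2, path$total)
  mid_knots_s <- cummax(mid_knots_s)
  s_pelvis <- approx(mid_knots_t, mid_knots_s, xout = t_grid, rule = 2)$y
  s_pelvis <- moving_average(s_pelvis, round(0.5 * params$sampling_rate))
  pt <- path$point(s_pelvis)
  hd <- path$heading(s_pelvis)
  nrm <- cbind(hd[, 1 + 1], -hd[, 1]) # rightward normal
  stride_period <- 2 * mean_step_time
  osc <- sin(2 * pi * t_grid / stride_period)
  pelvis_y <- 0.95 + 0.01 * sin(4 * pi * t_grid / stride_period)
  pelvis <- cbind(
    x = pt[, 1] + 0.015 * osc * nrm[, 1],
    y = pelvis_y,
    z = pt[, 2] + 0.015 * osc * nrm[, 2]
  )

  joints <- kinect_joints()
  X <- matrix(0, nf, 25L, dimnames = list(NULL, joints))
  Y <- X; Z <- X
  put <- function(j, m) {
    X[, j] <<- m[, 1]; Y[, j] <<- m[, 2]; Z[, j] <<- m[, 3]
  }
  # offsets (lateral, up, forward) from SpineBase, metres
  place_offset <- function(lat, up, fwd, swing = 0) {
    fo <- fwd + swing * 0.08 * osc
    cbind(
      x = pelvis[, 1] + lat * nrm[, 1] + fo * hd[, 1],
      y = pelvis[, 2] + up,
      z = pelvis[, 3] + lat * nrm[, 2] + fo * hd[, 2]
    )
  }
  put("SpineBase", pelvis)
  put("SpineMid", place_offset(0, 0.25, 0))
  put("SpineShoulder", place_offset(0, 0.45, 0))
  put("Neck", place_offset(0, 0.55, 0))
  put("Head", place_offset(0, 0.70, 0))
  put("ShoulderLeft", place_offset(-0.18, 0.45, 0))
  put("ShoulderRight", place_offset(0.18, 0.45, 0))
  put("ElbowLeft", place_offset(-0.20, 0.20, 0, swing = 1))
  put("ElbowRight", place_offset(0.20, 0.20, 0, swing = -1))
  put("WristLeft", place_offset(-0.21, 0.00, 0.05, swing = 1.6))
  put("WristRight", place_offset(0.21, 0.00, 0.05, swing = -1.6))
  put("HandLeft", place_offset(-0.21, -0.05, 0.08, swing = 1.8))
  put("HandRight", place_offset(0.21, -0.05, 0.08, swing = -1.8))
  put("HandTipLeft", place_offset(-0.21, -0.10, 0.10, swing = 1.8))
  put("HandTipRight", place_offset(0.21, -0.10, 0.10, swing = -1.8))
  put("ThumbLeft", place_offset(-0.18, -0.06, 0.09, swing = 1.8))
  put("ThumbRight", place_offset(0.18, -0.06, 0.09, swing = -1.8))
  put("HipLeft", place_offset(-0.09, -0.03, 0))
  put("HipRight", place_offset(0.09, -0.03, 0))
  put("FootLeft", left$xyz)
  put("FootRight", right$xyz)
  ankle_l <- left$xyz; ankle_l[, 2] <- ankle_l[, 2] + 0.07
  ankle_r <- right$xyz; ankle_r[, 2] <- ankle_r[, 2] + 0.07
  put("AnkleLeft", ankle_l)
  put("AnkleRight", ankle_r)
  hip_l <- place_offset(-0.09, -0.03, 0)
  hip_r <- place_offset(0.09, -0.03, 0)
  knee_lift <- matrix(rep(c(0, 0.02, 0), each = nf), nf, 3L)
  put("KneeLeft", (hip_l + ankle_l) / 2 + knee_lift)
  put("KneeRight", (hip_r + ankle_r) / 2 + knee_lift)

  if (params$noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, 2L), {
      array(rnorm(nf * 25L * 3L, 0, params$noise_sd), dim = c(nf, 25L, 3L))
    })
    X <- X + noise[, , 1]
    Y <- Y + noise[, , 2]
    Z <- Z + noise[, , 3]
    colnames(X) <- colnames(Y) <- colnames(Z) <- joints
  }

  rec <- skeletal_recording(
    positions = list(x = X, y = Y, z = Z),
    sampling_rate = params$sampling_rate,
    timestamps = t_grid,
    subject_id = subject_id, group = group,
    path_type = if (params$path == "straight") "straight" else "oval",
    filtered = FALSE
  )

  events <- tibble(
    index = sched$index,
    time = sched$t_contact,
    foot = sched$foot,
    step_length = sched$step_length,
    step_time = sched$step_time,
    width = sched$width,
    height = sched$height,
    s = sched$s
  )
  phases <- tibble(
    time_s = t_grid,
    left = ifelse(left$stance, "stance", "swing"),
    right = ifelse(right$stance, "stance", "swing")
  )
  realized_cadence <- 60 * (n_steps - 1) / (sched$t_contact[n_steps] - sched$t_contact[1])
  gt <- list(
    events = events,
    interior_events = events[2:(n_steps - 1L), , drop = FALSE],
    phases = phases,
    params = params,
    realized = list(
      n_steps = n_steps,
      cadence = realized_cadence,
      mean_step_length = mean(sched$step_length),
      stance_fraction = params$stance_fraction,
      path_length = path$total,
      duration = t_end
    )
  )
  list(recording = rec, ground_truth = gt)
}

#' Configuration of a synthetic two-group cohort
#'
#' Defaults emulate the group-level structure of an MCI gait study cohort
#' (30 HC vs 25 MCI) walking an oval course: demographics and confounders
#' (BMI, education, depression score) differ between groups, and the MCI
#' group walks with lower cadence, shorter steps, narrower oval stepping
#' width, longer relative stance and noisier timing. Each entry of
#' `hc`/`mci` is `c(mean, sd)` for a per-subject draw; scalar entries are
#' fixed for all subjects in the group.
#'
#' @param n_hc,n_mci Group sizes.
#' @param path `"oval"` or `"straight"` walking course.
#' @param hc,mci Named lists of per-group parameter distributions; see
#'   defaults. Walker fields: `cadence`, `step_length`, `step_width`,
#'   `step_height`, `stance_fraction`, `step_time_sd`, `step_length_sd`,
#'   `step_width_sd`, `step_height_sd`, `lr_asymmetry`, `noise_sd`. Demographic fields: `age`, `female_prop`,
#'   `bmi`, `education`, `mmse`, `moca`, `gds`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 30, n_mci = 25, path = c("oval", "straight"),
                          hc = list(), mci = list()) {
  path <- match.arg(path)
  # Group means/SDs of the walker parameters follow the oval-walking gait
  # table of the emulated study; within-subject SDs (step_time_sd,
  # step_length_sd, step_width_sd, step_height_sd) are set so the realized
  # per-trial variability features land near that table's variability rows
  # (e.g. step-time variability ~34% HC vs ~41% MCI, step-width ~57% vs
  # ~67%), which also reflects the turning segments of a real oval course.
  hc_default <- list(
    cadence = c(62.02, 9.73), step_length = c(0.3758, 0.0497),
    step_width = c(0.21, 0.04), step_height = c(0.12, 0.02),
    stance_fraction = c(0.60, 0.03), step_time_sd = c(0.30, 0.08),
    step_length_sd = c(0.13, 0.03), step_width_sd = c(0.11, 0.03),
    step_height_sd = c(0.045, 0.012), lr_asymmetry = c(1.03, 0.02),
    noise_sd = 0.003,
    age = c(68.33, 2.15), female_prop = 0.60, bmi = c(24.51, 2.67),
    education = c(13.53, 3.05), mmse = c(28.50, 1.17),
    moca = c(27.13, 2.05), gds = c(1.43, 1.33)
  )
  mci_default <- list(
    cadence = c(55.00, 11.67), step_length = c(0.3291, 0.0346),
    step_width = c(0.17, 0.03), step_height = c(0.13, 0.02),
    stance_fraction = c(0.64, 0.03), step_time_sd = c(0.38, 0.10),
    step_length_sd = c(0.15, 0.035), step_width_sd = c(0.12, 0.03),
    step_height_sd = c(0.055, 0.014), lr_asymmetry = c(1.08, 0.04),
    noise_sd = 0.003,
    age = c(69.76, 6.45), female_prop = 0.76, bmi = c(26.67, 2.62),
    education = c(11.56, 3.00), mmse = c(25.60, 1.29),
    moca = c(22.76, 1.69), gds = c(3.52, 1.29)
  )
  if (path == "straight") {
    # Straight-path contrasts: narrower stepping, larger step-length and
    # regularity contrasts, near-equal cadence, lower overall variability.
    hc_default[c("cadence", "step_length", "step_width", "step_height", "lr_asymmetry")] <-
      list(c(68.22, 10.55), c(0.3575, 0.0553), c(0.12, 0.03), c(0.11, 0.04), c(1.02, 0.02))
    mci_default[c("cadence", "step_length", "step_width", "step_height", "lr_asymmetry")] <-
      list(c(68.90, 9.70), c(0.3106, 0.0674), c(0.13, 0.03), c(0.08, 0.04), c(1.12, 0.05))
    hc_default[c("step_time_sd", "step_length_sd", "step_width_sd", "step_height_sd")] <-
      list(c(0.13, 0.05), c(0.07, 0.02), c(0.035, 0.01), c(0.03, 0.01))
    mci_default[c("step_time_sd", "step_length_sd", "step_width_sd", "step_height_sd")] <-
      list(c(0.20, 0.06), c(0.10, 0.03), c(0.03, 0.01), c(0.035, 0.012))
  }
  structure(
    list(
      n_hc = n_hc, n_mci = n_mci, path = path,
      hc = utils::modifyList(hc_default, hc),
      mci = utils::modifyList(mci_default, mci)
    ),
    class = "cohort_config"
  )
}

draw1 <- function(spec, lower = -Inf) {
  if (length(spec) == 1L) {
    return(spec)
  }
  max(spec[1] + rnorm(1) * spec[2], lower)
}

#' Simulate a two-group cohort of walking recordings
#'
#' Draws per-subject walker parameters and demographics from the per-group
#' distributions of a [cohort_config()], simulates every recording with
#' [generate_recording()], and returns a manifest plus recordings and ground
#' truths. Subject seeds are derived from `seed` and the subject index, so
#' any subject can be regenerated independently.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, recordings are written as
#'   CSV, ground truths as JSON, and the manifest as `manifest.csv`.
#' @return A list with `manifest` (tibble), `recordings` (named list of
#'   [skeletal_recording()]), and `ground_truth` (named list).
#' @export
generate_cohort <- function(config, seed, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_hc < 1 || config$n_mci < 1) {
    abort("Both groups must have at least one subject.")
  }
  groups <- c(rep("HC", config$n_hc), rep("MCI", config$n_mci))
  n <- length(groups)
  recordings <- vector("list", n)
  gts <- vector("list", n)
  rows <- vector("list", n)

  for (i in seq_len(n)) {
    g <- groups[i]
    gp <- if (g == "HC") config$hc else config$mci
    sid <- sprintf("%s%03d", tolower(g), i)
    subj <- with_seed(derive_seed(seed, 10L, i), {
      list(
        cadence = draw1(gp$cadence, lower = 30),
        step_length = draw1(gp$step_length, lower = 0.15),
        step_width = draw1(gp$step_width, lower = 0.05),
        step_height = draw1(gp$step_height, lower = 0.03),
        stance_fraction = min(max(draw1(gp$stance_fraction), 0.52), 0.75),
        step_time_sd = draw1(gp$step_time_sd, lower = 0.005),
        step_length_sd = draw1(gp$step_length_sd, lower = 0.005),
        step_width_sd = draw1(gp$step_width_sd %||% 0.02, lower = 0.002),
        step_height_sd = draw1(gp$step_height_sd %||% 0.015, lower = 0.002),
        lr_asymmetry = draw1(gp$lr_asymmetry, lower = 1.0),
        noise_sd = if (length(gp$noise_sd) == 1L) gp$noise_sd else draw1(gp$noise_sd, 0),
        age = draw1(gp$age, lower = 60),
        gender = if (runif(1) < gp$female_prop) "female" else "male",
        bmi = draw1(gp$bmi, lower = 15),
        education = draw1(gp$education, lower = 0),
        mmse = min(draw1(gp$mmse, lower = 0), 30),
        moca = min(draw1(gp$moca, lower = 0), 30),
        gds = draw1(gp$gds, lower = 0)
      )
    })
    wp <- walker_params(
      cadence = subj$cadence,
      step_length_mean = subj$step_length,
      step_length_sd = subj$step_length_sd,
      step_time_sd = subj$step_time_sd,
      stance_fraction = subj$stance_fraction,
      step_width_mean = subj$step_width,
      step_width_sd = subj$step_width_sd,
      step_height_mean = subj$step_height,
      step_height_sd = subj$step_height_sd,
      lr_asymmetry = subj$lr_asymmetry,
      noise_sd = subj$noise_sd,
      path = config$path
    )
    sim <- generate_recording(wp, seed = derive_seed(seed, 20L, i),
                              subject_id = sid, group = g)
    recordings[[i]] <- sim$recording
    gts[[i]] <- sim$ground_truth
    rows[[i]] <- tibble(
      subject_id = sid, group = g,
      age = subj$age, gender = subj$gender, bmi = subj$bmi,
      education_years = subj$education, gds = subj$gds,
      mmse = subj$mmse, moca = subj$moca,
      recording_path = NA_character_,
      path_type = if (config$path == "straight") "straight" else "oval"
    )
  }
  manifest <- list_rbind(rows)
  names(recordings) <- manifest$subject_id
  names(gts) <- manifest$subject_id

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      f <- file.path(out_dir, paste0(manifest$subject_id[i], ".csv"))
      write_recording(recordings[[i]], f, dialect = "csv")
      manifest$recording_path[i] <- f
      gt <- gts[[i]]
      jsonlite::write_json(
        list(events = gt$events, realized = gt$realized),
        file.path(out_dir, paste0(manifest$subject_id[i], "_truth.json")),
        auto_unbox = TRUE, digits = NA
      )
    }
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(manifest = manifest, recordings = recordings, ground_truth = gts)
}

#' Simulate a cohort and extract its gait feature table
#'
#' Convenience wrapper running the in-memory pipeline: simulate with
#' [generate_cohort()], low-pass filter each recording, extract the
#' 50-feature roster, and join with demographics into a cohort table ready
#' for [compare_groups()] or [run_cv_experiment()].
#'
#' @inheritParams generate_cohort
#' @param ... Passed to [lowpass_filter()].
#' @return A tibble: one row per subject with 50 feature columns,
#'   demographics, confounders and `group`.
#' @export
simulate_cohort_features <- function(config, seed, ...) {
  sim <- generate_cohort(config, seed)
  feats <- imap(sim$recordings, function(rec, sid) {
    fv <- extract_features(lowpass_filter(rec, ...))
    wide <- tidyr::pivot_wider(
      fv[, c("feature", "value")],
      names_from = "feature", values_from = "value"
    )
    dplyr::bind_cols(tibble(subject_id = sid), wide)
  }) |> list_rbind()
  dplyr::left_join(
    sim$manifest[, setdiff(names(sim$manifest), "recording_path")],
    feats,
    by = "subject_id"
  )
}
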