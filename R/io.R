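#' Read a skeletal recording from disk
#'
#' Two plain-text dialects are supported. The CSV dialect is a long table
#' with header `time_s,joint,x_m,y_m,z_m`, one row per joint per frame. The
#' JSON dialect stores a metadata object plus per-joint coordinate arrays.
#' Trial metadata (subject, group, path type) lives in the cohort manifest
#' for CSV files and can be overridden via the arguments below.
#'
#' @param path File to read.
#' @param dialect `"csv"` or `"json"`; defaults from the file extension.
#' @param sampling_rate Sampling rate in Hz; for CSV inputs, inferred from
#'   the median timestamp spacing when `NULL`.
#' @param subject_id,group,path_type Trial metadata (CSV dialect; the JSON
#'   dialect carries its own).
#'
#' @return A [skeletal_recording()].
#' @export
read_recording <- function(path, dialect = c("auto", "csv", "json"),
                           sampling_rate = NULL, subject_id = "unknown",
                           group = "unknown", path_type = "straight") {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort(paste0("Recording file not found: ", path))
  if (dialect == "json") {
    return(read_recording_json(path))
  }

  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("time_s", "joint", "x_m", "y_m", "z_m")
  if (!all(required %in% names(df))) {
    abort(paste0(
      "CSV recording must have columns ", paste(required, collapse = ", "),
      "; found: ", paste(names(df), collapse = ", ")
    ))
  }
  joints <- kinect_joints()
  bad <- which(!df$joint %in% joints)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Unknown joint label '%s' at data row %d of %s.",
      df$joint[bad[1]], bad[1], path
    ))
  }
  times <- sort(unique(df$time_s))
  counts <- table(factor(df$joint, levels = joints))
  if (any(counts != length(times))) {
    missing_j <- names(counts)[counts < length(times)][1]
    abort(sprintf(
      "Joint '%s' is missing from %d frame(s) of %s (each frame needs all 25 joints).",
      missing_j, length(times) - counts[[missing_j]], path
    ))
  }
  if (any(diff(times) <= 0)) abort(paste0("Non-monotone timestamps in ", path))

  wide <- function(coord) {
    m <- matrix(NA_real_, nrow = length(times), ncol = 25L,
                dimnames = list(NULL, joints))
    m[cbind(match(df$time_s, times), match(df$joint, joints))] <- df[[coord]]
    m
  }
  if (is.null(sampling_rate)) {
    sampling_rate <- if (length(times) > 1L) 1 / median(diff(times)) else 30
  }
  skeletal_recording(
    positions = list(x = wide("x_m"), y = wide("y_m"), z = wide("z_m")),
    sampling_rate = sampling_rate, timestamps = times,
    subject_id = subject_id, group = group, path_type = path_type
  )
}

read_recording_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- obj$metadata
  pos <- lapply(c(x = "x", y = "y", z = "z"), function(coord) {
    m <- sapply(kinect_joints(), function(j) {
      v <- obj$joints[[j]][[coord]]
      if (is.null(v)) abort(sprintf("Joint '%s' missing from %s.", j, path))
      as.numeric(v)
    })
    matrix(m, ncol = 25L, dimnames = list(NULL, kinect_joints()))
  })
  rec <- skeletal_recording(
    positions = pos,
    sampling_rate = meta$sampling_rate,
    timestamps = as.numeric(obj$time_s),
    subject_id = meta$subject_id %||% "unknown",
    group = meta$group %||% "unknown",
    path_type = meta$path_type %||% "straight",
    filtered = isTRUE(meta$filtered)
  )
  rec
}

#' Write a skeletal recording to disk
#'
#' Inverse of [read_recording()]; both dialects round-trip coordinates to
#' within 1e-9 m.
#'
#' @param rec A [skeletal_recording()].
#' @param path Destination file.
#' @param dialect `"csv"` or `"json"`; defaults from the file extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("auto", "csv", "json")) {
  validate_recording(rec)
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (dialect == "csv") {
    df <- as_tibble(rec)
    readr::write_csv(df, path, progress = FALSE)
  } else {
    joints <- kinect_joints()
    obj <- list(
      metadata = list(
        subject_id = rec$subject_id, group = rec$group,
        path_type = rec$path_type, sampling_rate = rec$sampling_rate,
        filtered = rec$filtered
      ),
      time_s = rec$timestamps,
      joints = setNames(lapply(joints, function(j) {
        list(x = unname(rec$x[, j]), y = unname(rec$y[, j]), z = unname(rec$z[, j]))
      }), joints)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest lists one subject per row with demographics, confounders and
#' the path to each recording:
#' `subject_id,group,age,gender,bmi,education_years,gds,mmse,moca,recording_path,path_type`.
#'
#' @param path Manifest CSV file.
#' @return A tibble, one row per subject x trial.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("Manifest not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c(
    "subject_id", "group", "age", "gender", "bmi", "education_years",
    "gds", "mmse", "moca", "recording_path", "path_type"
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(paste0("Manifest is missing column(s): ", paste(missing, collapse = ", ")))
  }
  as_tibble(df)
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}
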