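#' Zero-phase Butterworth low-pass filtering of a recording
#'
#' Each of the 75 coordinate channels (25 joints x 3 axes) is filtered
#' independently with an order-`order` Butterworth low-pass applied forward
#' and backward (zero phase), so detected gait-event times are not biased by
#' filter delay. Because the filter runs twice, the effective magnitude
#' response is |H(f)|^2 = 1 / (1 + (f / cutoff)^(2 * order)).
#'
#' Edge transients are suppressed by odd-reflection padding of three filter
#' lengths at each end. Non-uniform timestamps are first resampled to a
#' uniform grid via [resample_uniform()].
#'
#' @param rec A [skeletal_recording()], not yet filtered.
#' @param order Filter order (default 6).
#' @param cutoff_hz Cut-off frequency in Hz (default 3); must be below the
#'   Nyquist frequency `sampling_rate / 2`.
#' @return The filtered recording, with its `filtered` flag set.
#' @export
#' @examples
#' rec <- generate_recording(walker_params(path_length_m = 5), seed = 1)$recording
#' filt <- lowpass_filter(rec)
lowpass_filter <- function(rec, order = 6L, cutoff_hz = 3.0) {
  validate_recording(rec)
  if (isTRUE(rec$filtered)) {
    abort("Recording is already filtered; refusing to filter twice.")
  }
  nyquist <- rec$sampling_rate / 2
  if (cutoff_hz >= nyquist) {
    abort(sprintf(
      "cutoff_hz (%.2f Hz) must be below the Nyquist frequency (%.2f Hz).",
      cutoff_hz, nyquist
    ))
  }
  if (!is_uniform(rec)) rec <- resample_uniform(rec)

  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  out <- rec
  for (coord in c("x", "y", "z")) {
    out[[coord]] <- apply(rec[[coord]], 2, filtfilt_reflect, bf = bf)
  }
  out$filtered <- TRUE
  out
}

# Forward-backward filtering with odd (point-reflection) extension of
# 3 * filter length at each end. Each pass is seeded with a steady-state
# history at the first extended sample, so constant signals pass through
# exactly and edge transients are confined to the discarded padding.
filtfilt_reflect <- function(x, bf) {
  n <- length(x)
  np <- max(length(bf$b), length(bf$a)) - 1L
  padlen <- 3L * np
  if (n <= padlen) {
    abort("Signal too short for the requested filter order.")
  }
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  ext <- c(pre, x, post)
  pass <- function(v) {
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1], np), init.y = rep(v[1], np)))
  }
  y <- rev(pass(rev(pass(ext))))
  y[(padlen + 1L):(padlen + n)]
}
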