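#' Plot a skeletal recording
#'
#' Overhead (x-z) view of the foot and SpineBase trajectories, the most
#' useful diagnostic for walking trials.
#'
#' @param object A [skeletal_recording()].
#' @param joints Joints to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.skeletal_recording <- function(object,
                                        joints = c("FootLeft", "FootRight", "SpineBase"),
                                        ...) {
  df <- as_tibble(object) |>
    filter(.data$joint %in% joints)
  ggplot(df, aes(x = .data$x_m, y = .data$z_m, colour = .data$joint)) +
    geom_path(alpha = 0.8) +
    coord_equal() +
    labs(
      x = "x (lateral, m)", y = "z (progression, m)",
      title = sprintf("Subject %s (%s path)", object$subject_id, object$path_type)
    ) +
    theme_minimal()
}

#' Plot the inter-foot distance signal with detected step events
#'
#' @param d A [foot_distance_signal()] tibble.
#' @param events Optionally, a [detect_step_events()] tibble to overlay.
#' @return A ggplot.
#' @export
plot_distance_signal <- function(d, events = NULL) {
  p <- ggplot(d, aes(x = .data$time_s, y = .data$distance_m)) +
    geom_line(colour = "grey30") +
    labs(x = "time (s)", y = "inter-foot distance (m)") +
    theme_minimal()
  if (!is.null(events)) {
    p <- p + geom_point(
      data = events,
      aes(x = .data$time, y = .data$peak_distance, colour = .data$leading_foot),
      size = 2
    ) +
      labs(colour = "leading foot")
  }
  p
}

#' Plot a random-forest importance ranking
#'
#' Bar chart of mean normalised impurity importances with the retention
#' threshold drawn as a dashed line.
#'
#' @param object A `gait_importance` from [rf_feature_importance()].
#' @param top_n Number of features to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gait_importance <- function(object, top_n = 20, ...) {
  df <- utils::head(object, top_n)
  ggplot(df, aes(x = stats::reorder(.data$feature, .data$importance),
                 y = .data$importance, fill = .data$retained)) +
    geom_col() +
    geom_hline(yintercept = attr(object, "threshold"),
               linetype = "dashed", colour = "purple") +
    coord_flip() +
    labs(x = NULL, y = "mean RF importance (normalised)", fill = "retained") +
    theme_minimal()
}

#' Plot pooled metrics of one or more evaluation reports
#'
#' @param object A `gait_eval_report`, or a list of them.
#' @param ... Further reports.
#' @return A ggplot.
#' @export
autoplot.gait_eval_report <- function(object, ...) {
  reports <- c(list(object), Filter(function(o) inherits(o, "gait_eval_report"), list(...)))
  df <- list_rbind(map(reports, tidy))
  ggplot(df, aes(x = .data$metric, y = .data$value, fill = .data$classifier)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "percent") +
    theme_minimal()
}
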