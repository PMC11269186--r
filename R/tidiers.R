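#' Tidy a cross-validation evaluation report
#'
#' @param x A `gait_eval_report` from [run_cv_experiment()].
#' @param ... Unused.
#' @return A long tibble with one row per metric (pooled out-of-fold).
#' @export
tidy.gait_eval_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value") |>
    dplyr::mutate(classifier = x$kind, .before = 1)
}

#' @rdname tidy.gait_eval_report
#' @return For `glance()`: a one-row tibble with classifier, seed, n,
#'   confusion counts and the pooled metrics.
#' @export
glance.gait_eval_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      classifier = x$kind, seed = x$seed, n = x$n,
      tp = x$confusion[["tp"]], fn = x$confusion[["fn"]],
      tn = x$confusion[["tn"]], fp = x$confusion[["fp"]]
    ),
    x$metrics
  )
}

#' Tidy a feature-selection result
#'
#' @param x A `gait_selection` from [select_features()].
#' @param ... Unused.
#' @return The per-feature decision tibble (p-value, kept, reason).
#' @export
tidy.gait_selection <- function(x, ...) {
  x$decisions
}

#' @rdname tidy.gait_selection
#' @export
glance.gait_selection <- function(x, ...) {
  tibble(
    n_significant = length(x$significant),
    n_selected = length(x$selected)
  )
}
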