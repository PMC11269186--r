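#' Specify a classifier and its hyperparameter grid
#'
#' Three classical classifiers are supported: ridge-penalised logistic
#' regression, a support vector machine (linear or RBF kernel) and a random
#' forest. Default grids cover the usual operating ranges; any tibble with
#' the same columns can be supplied to override them.
#'
#' @param kind `"logistic_regression"`, `"svm"` or `"random_forest"`.
#' @param grid Optional hyperparameter grid (tibble). Columns:
#'   `lambda` (LR); `kernel`, `cost`, `gamma` (SVM, `gamma = NA` for
#'   linear, `"scale"` for 1 / (p * mean variance)); `num_trees`,
#'   `max_depth` (0 = unlimited), `min_node`, `mtry` (`"sqrt"` or a
#'   fraction) for RF.
#' @param seed Integer seed recorded in every report; folds, inner splits
#'   and model seeds all derive from it.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("logistic_regression", "svm", "random_forest"),
                            grid = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- switch(kind,
      logistic_regression = tibble(lambda = c(0.01, 0.1, 1, 10)),
      svm = dplyr::bind_rows(
        tidyr::expand_grid(kernel = "linear", cost = c(0.1, 1, 10, 100),
                           gamma = NA_character_),
        tidyr::expand_grid(kernel = "rbf", cost = c(0.1, 1, 10, 100),
                           gamma = c("scale", "0.01", "0.1"))
      ),
      # validation ties are broken toward earlier rows, so rows are ordered
      # by a priori preference: more trees and unconstrained depth first
      random_forest = tidyr::expand_grid(
        num_trees = c(500L, 300L, 100L),
        max_depth = c(0L, 5L, 3L),
        min_node = c(1L, 2L, 4L),
        mtry = c("sqrt", "0.5")
      )
    )
  }
  if (nrow(grid) == 0L) abort("Hyperparameter grid must be non-empty.")
  structure(list(kind = kind, grid = as_tibble(grid), seed = as.integer(seed)),
            class = "classifier_spec")
}

# Stratified fold assignment; deterministic given seed.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  fold
}

fit_predict <- function(kind, row, x_train, y_train, x_test, seed) {
  if (kind == "logistic_regression") {
    if (ncol(x_train) == 1L) {
      # glmnet requires >= 2 columns; a zero column changes nothing
      x_train <- cbind(x_train, .dummy = 0)
      x_test <- cbind(x_test, .dummy = 0)
    }
    lam <- sort(unique(c(row$lambda, row$lambda * c(10, 100))), decreasing = TRUE)
    fit <- glmnet::glmnet(x_train, y_train, family = "binomial", alpha = 0,
                          lambda = lam)
    pred <- drop(predict(fit, x_test, s = row$lambda, type = "class"))
    list(pred = factor(pred, levels = levels(y_train)), model = fit)
  } else if (kind == "svm") {
    g <- row$gamma
    gamma_val <- if (is.na(g) || identical(g, "scale")) {
      v <- mean(apply(x_train, 2, var))
      1 / (ncol(x_train) * max(v, 1e-12))
    } else {
      as.numeric(g)
    }
    fit <- e1071::svm(
      x_train, y_train,
      kernel = if (row$kernel == "rbf") "radial" else "linear",
      cost = row$cost, gamma = gamma_val, scale = FALSE
    )
    list(pred = predict(fit, x_test), model = fit)
  } else {
    mtry <- if (identical(row$mtry, "sqrt")) {
      max(1L, floor(sqrt(ncol(x_train))))
    } else {
      max(1L, floor(as.numeric(row$mtry) * ncol(x_train)))
    }
    fit <- ranger::ranger(
      x = x_train, y = y_train,
      num.trees = row$num_trees, max.depth = row$max_depth,
      min.node.size = row$min_node, mtry = mtry,
      importance = "impurity", seed = seed,
      num.threads = 1L, verbose = FALSE
    )
    # seed the prediction too: ranger breaks 50/50 vote ties randomly
    list(pred = predict(fit, data = x_test, num.threads = 1L,
                        seed = seed)$predictions,
         model = fit)
  }
}

#' Nested cross-validated classification of HC vs MCI
#'
#' The evaluation protocol: stratified 5-fold outer cross-validation; inside
#' each fold, confounder adjustment and (for LR/SVM) statistical feature
#' selection are fitted on the training portion only, the training portion
#' is split 80/20 into an inner training and validation set, every grid row
#' is scored on the validation set, and the winning configuration is refit
#' on the full training portion to predict the held-out fold. Metrics are
#' computed from the pooled out-of-fold predictions with MCI as the
#' positive class. Features are z-scored with training statistics for LR
#' and SVM; the random forest sees unstandardised features and, by default,
#' all 50 of them.
#'
#' @param table A cohort tibble: feature columns (see [feature_roster()]),
#'   optional covariates, and a two-level `group` column containing
#'   `"MCI"`.
#' @param spec A [classifier_spec()].
#' @param use_statistical_selection Run in-fold [compare_groups()] +
#'   [select_features()]? Defaults to `TRUE` except for the random forest.
#' @param k Number of outer folds (default 5).
#' @param inner_train_frac Inner split fraction (default 0.8).
#' @param adjust_covariates Fit ANCOVA adjustment in-fold when the
#'   covariate columns are present (default `TRUE`).
#' @param covariates Covariates for the in-fold adjustment.
#' @param alpha,r_threshold In-fold selection parameters.
#' @return A `gait_eval_report`: pooled confusion counts and metrics,
#'   per-fold metrics, chosen hyperparameters and selected features, the
#'   out-of-fold predictions, and (for RF) the per-fold fitted models.
#' @export
run_cv_experiment <- function(table, spec,
                              use_statistical_selection = spec$kind != "random_forest",
                              k = 5L, inner_train_frac = 0.8,
                              adjust_covariates = TRUE,
                              covariates = c("bmi", "education_years", "gds"),
                              alpha = 0.05, r_threshold = 0.90) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- intersect(feature_roster()$feature, names(table))
  if (length(features) == 0L) abort("No roster feature columns found in `table`.")
  groups <- sort(unique(as.character(table$group)))
  if (length(groups) != 2L) abort("`group` must have exactly 2 levels.")
  positive <- if ("MCI" %in% groups) "MCI" else groups[2]
  y <- factor(as.character(table$group), levels = c(setdiff(groups, positive), positive))
  if (min(table(y)) < k) {
    abort(sprintf("Each class needs at least %d subjects for stratified %d-fold CV.", k, k))
  }
  do_adjust <- adjust_covariates && all(covariates %in% names(table))

  fold <- stratified_folds(y, k, derive_seed(spec$seed, 1L))
  scale_features <- spec$kind %in% c("logistic_regression", "svm")

  preds <- vector("list", k)
  fold_info <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    tr <- table[tr_idx, , drop = FALSE]
    te <- table[te_idx, , drop = FALSE]

    # training-fold median imputation
    for (col in features) {
      med <- median(tr[[col]], na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      tr[[col]][!is.finite(tr[[col]])] <- med
      te[[col]][!is.finite(te[[col]])] <- med
    }

    if (do_adjust) {
      adj_fit <- tryCatch(
        ancova_coefficients(tr, covariates, features = features),
        error = function(e) NULL # rank-deficient fold: skip adjustment
      )
      if (!is.null(adj_fit)) {
        tr <- apply_ancova(tr, adj_fit, features)
        te <- apply_ancova(te, adj_fit, features)
      }
    }

    used <- features
    if (use_statistical_selection) {
      st <- compare_groups(tr, features = features)
      sel <- select_features(st, tr, r_threshold = r_threshold, alpha = alpha)
      if (length(sel$selected) == 0L) {
        warn(sprintf("Fold %d: selection kept 0 features; falling back to all.", f))
      } else {
        used <- sel$selected
      }
    }

    x_tr <- as.matrix(tr[, used])
    x_te <- as.matrix(te[, used])
    if (scale_features) {
      mu <- colMeans(x_tr)
      sig <- apply(x_tr, 2, sd)
      sig[sig == 0 | !is.finite(sig)] <- 1
      x_tr <- sweep(sweep(x_tr, 2, mu), 2, sig, "/")
      x_te <- sweep(sweep(x_te, 2, mu), 2, sig, "/")
    }
    y_tr <- y[tr_idx]

    # single stratified 80/20 inner split for grid search
    inner_fold <- stratified_folds(
      y_tr, 5L, derive_seed(spec$seed, 2L, f)
    )
    val <- inner_fold == 1L # ~20%
    if (length(unique(y_tr[!val])) < 2L || length(unique(y_tr[val])) < 2L) {
      val <- seq_along(y_tr) %in% utils::head(order(inner_fold), ceiling(0.2 * length(y_tr)))
    }
    scores <- vapply(seq_len(nrow(spec$grid)), function(gi) {
      row <- spec$grid[gi, ]
      out <- fit_predict(spec$kind, row, x_tr[!val, , drop = FALSE],
                         y_tr[!val], x_tr[val, , drop = FALSE],
                         seed = derive_seed(spec$seed, 3L, f, gi))
      mean(out$pred == y_tr[val])
    }, numeric(1))
    best <- which.max(scores) # ties: first grid row

    refit <- fit_predict(spec$kind, spec$grid[best, ], x_tr, y_tr, x_te,
                         seed = derive_seed(spec$seed, 4L, f))
    preds[[f]] <- tibble(
      row = te_idx,
      subject_id = if ("subject_id" %in% names(table)) table$subject_id[te_idx] else as.character(te_idx),
      fold = f,
      truth = as.character(y[te_idx]),
      pred = as.character(refit$pred)
    )
    fold_info[[f]] <- list(
      fold = f,
      best_params = as.list(spec$grid[best, ]),
      validation_accuracy = scores[best],
      features = used
    )
    models[[f]] <- if (spec$kind == "random_forest") refit$model else NULL
  }

  predictions <- list_rbind(preds)
  tp <- sum(predictions$truth == positive & predictions$pred == positive)
  fn <- sum(predictions$truth == positive & predictions$pred != positive)
  tn <- sum(predictions$truth != positive & predictions$pred != positive)
  fp <- sum(predictions$truth != positive & predictions$pred == positive)
  per_fold <- list_rbind(map(seq_len(k), function(f) {
    p <- predictions[predictions$fold == f, ]
    dplyr::bind_cols(tibble(fold = f), compute_metrics(
      tp = sum(p$truth == positive & p$pred == positive),
      fn = sum(p$truth == positive & p$pred != positive),
      tn = sum(p$truth != positive & p$pred != positive),
      fp = sum(p$truth != positive & p$pred == positive)
    ))
  }))

  structure(
    list(
      kind = spec$kind,
      seed = spec$seed,
      positive = positive,
      confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
      metrics = compute_metrics(tp, fn, tn, fp),
      per_fold_metrics = per_fold,
      folds = fold_info,
      predictions = predictions,
      models = models,
      n = nrow(table)
    ),
    class = "gait_eval_report"
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (MCI recall), precision, specificity and F-score,
#' all in percent. Ratios with a zero denominator are returned as `NA`.
#'
#' @param tp,fn,tn,fp Confusion counts (positive class = MCI).
#' @return A one-row tibble with the five metrics in percent.
#' @export
#' @examples
#' compute_metrics(tp = 8, fn = 2, tn = 9, fp = 1)
compute_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0)) abort("Confusion counts must be non-negative.")
  total <- sum(counts)
  if (total == 0) abort("Confusion counts sum to zero.")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  prec <- ratio(tp, tp + fp)
  f <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  tibble(
    accuracy = 100 * (tp + tn) / total,
    sensitivity = 100 * sens,
    precision = 100 * prec,
    specificity = 100 * ratio(tn, tn + fp),
    f_score = 100 * f
  )
}

#' @export
print.gait_eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<gait_eval_report> %s (seed %d, n = %d, positive = %s)\n  accuracy %.1f%% | sensitivity %.1f%% | precision %.1f%% | specificity %.1f%% | F %.1f%%\n",
    x$kind, x$seed, x$n, x$positive,
    m$accuracy, m$sensitivity, m$precision, m$specificity, m$f_score
  ))
  invisible(x)
}

#' Random-forest feature importance ranking
#'
#' Impurity-decrease importances from the per-fold random forests of a
#' cross-validation run, normalised to sum to one per fit, averaged across
#' folds, and thresholded into a retained feature set.
#'
#' @param table A cohort tibble (used when `report` is not supplied).
#' @param spec A [classifier_spec()] of kind `"random_forest"`.
#' @param threshold Retention threshold on the mean importance score
#'   (default 0.03).
#' @param report Optionally, an existing `gait_eval_report` from
#'   [run_cv_experiment()] with the same spec.
#' @return A tibble of class `gait_importance`: `feature`, `importance`
#'   (mean normalised score), `retained`.
#' @export
rf_feature_importance <- function(table, spec, threshold = 0.03, report = NULL) {
  if (!inherits(spec, "classifier_spec") || spec$kind != "random_forest") {
    abort("rf_feature_importance() needs a random_forest classifier_spec.")
  }
  if (is.null(report)) {
    report <- run_cv_experiment(table, spec, use_statistical_selection = FALSE)
  }
  models <- report$models[!vapply(report$models, is.null, logical(1))]
  if (length(models) == 0L) abort("Report contains no fitted random forests.")
  per_fit <- map(models, function(m) {
    imp <- ranger::importance(m)
    imp <- pmax(imp, 0)
    imp / sum(imp)
  })
  all_feats <- sort(unique(unlist(map(per_fit, names))))
  mat <- vapply(per_fit, function(v) {
    out <- setNames(numeric(length(all_feats)), all_feats)
    out[names(v)] <- v
    out
  }, numeric(length(all_feats)))
  mean_imp <- rowMeans(mat)
  out <- tibble(
    feature = names(mean_imp),
    importance = unname(mean_imp),
    retained = unname(mean_imp) > threshold
  ) |>
    arrange(dplyr::desc(.data$importance))
  class(out) <- c("gait_importance", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "seed") <- spec$seed
  out
}
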