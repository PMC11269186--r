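#' Remove confounder effects from gait features (ANCOVA adjustment)
#'
#' Each feature is fit by least squares on the covariates plus the group
#' factor (the ANCOVA model), and the fitted covariate contribution is
#' subtracted, re-centred on the pooled grand mean. Including group in the
#' model matters when the confounders themselves differ between groups:
#' a covariates-only fit would absorb part of the genuine group effect
#' into the covariate coefficients and remove it. Only covariate terms are
#' subtracted, so no group information leaks into the adjusted values, and
#' adjusting twice is a no-op.
#'
#' @param table A cohort tibble: one row per subject, feature columns plus
#'   covariates and `group`.
#' @param covariates Covariate column names (default BMI, education years
#'   and depression score, the confounders that differ between groups).
#' @param features Feature columns to adjust; defaults to the 50-feature
#'   roster columns present in `table`.
#' @return `table` with the feature columns replaced by adjusted values.
#' @export
ancova_adjust <- function(table, covariates = c("bmi", "education_years", "gds"),
                          features = NULL) {
  features <- features %||% intersect(feature_roster()$feature, names(table))
  fit <- ancova_coefficients(table, covariates)
  apply_ancova(table, fit, features)
}

# Fit the ANCOVA model (intercept + covariates + group, when present) on
# `table`; returns the pieces needed to adjust any table with the same
# covariate columns.
ancova_coefficients <- function(table, covariates,
                                features = intersect(feature_roster()$feature, names(table))) {
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov) > 0L) {
    abort(paste0("Covariate(s) not in table: ", paste(missing_cov, collapse = ", ")))
  }
  X <- as.matrix(table[, covariates])
  if (!is.numeric(X)) abort("Covariates must be numeric.")
  Xc <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    dropped <- colnames(Xc)[qrX$pivot[(qrX$rank + 1L):ncol(Xc)]]
    abort(paste0(
      "Covariate matrix is rank deficient; collinear covariate(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  design <- Xc
  if ("group" %in% names(table)) {
    g <- as.character(table$group)
    lv <- sort(unique(g))
    if (length(lv) == 2L) {
      design <- cbind(Xc, group = as.numeric(g == lv[2]))
    }
  }
  beta <- map(features, function(f) {
    y <- table[[f]]
    ok <- is.finite(y)
    if (sum(ok) <= ncol(design)) {
      return(NULL)
    }
    fit <- lm.fit(design[ok, , drop = FALSE], y[ok])
    b <- fit$coefficients[colnames(Xc)[-1]]
    b[is.na(b)] <- 0
    list(beta_cov = b, center = mean(drop(X[ok, , drop = FALSE] %*% b)))
  })
  names(beta) <- features
  list(covariates = covariates, beta = beta)
}

# Subtract the fitted covariate contribution (re-centred) from each feature.
apply_ancova <- function(table, fit, features = names(fit$beta)) {
  X <- as.matrix(table[, fit$covariates])
  for (f in features) {
    b <- fit$beta[[f]]
    if (is.null(b)) next
    y <- table[[f]]
    ok <- is.finite(y)
    table[[f]][ok] <- y[ok] - drop(X[ok, , drop = FALSE] %*% b$beta_cov) + b$center
  }
  table
}

#' Compare gait features between groups with normality-routed tests
#'
#' For each feature, a Shapiro-Wilk normality test is run within each group.
#' If both groups look normal (p >= `alpha_normality`) the groups are
#' compared with a two-sided Welch t-test; otherwise with a two-sided
#' Mann-Whitney U test.
#'
#' @param table A cohort tibble with a two-level `group` column.
#' @param features Feature columns to test; defaults to the roster columns
#'   present in `table`.
#' @param alpha_normality Shapiro-Wilk significance level (default 0.05).
#' @return A tibble: `feature`, `route` (`"t_test"` / `"mann_whitney"`),
#'   `p_value`, per-group means and SDs, Shapiro-Wilk p-values.
#' @export
compare_groups <- function(table, features = NULL, alpha_normality = 0.05) {
  groups <- sort(unique(as.character(table$group)))
  if (length(groups) != 2L) abort("`group` must have exactly 2 levels.")
  features <- features %||% intersect(feature_roster()$feature, names(table))
  g1 <- table$group == groups[1]
  rows <- map(features, function(f) {
    x <- table[[f]][g1]
    y <- table[[f]][!g1]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 3L || length(y) < 3L) {
      return(NULL) # skipped: too few observations
    }
    sw1 <- if (sd(x) == 0) 0 else shapiro.test(x)$p.value
    sw2 <- if (sd(y) == 0) 0 else shapiro.test(y)$p.value
    normal <- sw1 >= alpha_normality && sw2 >= alpha_normality
    p <- if (normal) {
      t.test(x, y, var.equal = FALSE)$p.value
    } else {
      suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    }
    tibble(
      feature = f,
      route = if (normal) "t_test" else "mann_whitney",
      p_value = p,
      mean_1 = mean(x), sd_1 = sd(x),
      mean_2 = mean(y), sd_2 = sd(y),
      shapiro_p_1 = sw1, shapiro_p_2 = sw2
    )
  })
  out <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  names(out)[names(out) == "mean_1"] <- paste0("mean_", groups[1])
  names(out)[names(out) == "sd_1"] <- paste0("sd_", groups[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", groups[2])
  names(out)[names(out) == "sd_2"] <- paste0("sd_", groups[2])
  names(out)[names(out) == "shapiro_p_1"] <- paste0("shapiro_p_", groups[1])
  names(out)[names(out) == "shapiro_p_2"] <- paste0("shapiro_p_", groups[2])
  out
}

#' Two-phase statistical feature selection
#'
#' Phase 1 keeps features with `p_value < alpha`. Phase 2 prunes
#' redundancy: walking the significant features in ascending p order (ties
#' broken by canonical roster order), each feature is accepted unless its
#' absolute Pearson correlation with an already-accepted feature exceeds
#' `r_threshold`, in which case it is dropped in favour of that lower-p
#' representative.
#'
#' @param stats A [compare_groups()] result.
#' @param table The cohort tibble the tests were computed on.
#' @param r_threshold Correlation-pruning threshold (default 0.90).
#' @param alpha Significance threshold (default 0.05).
#' @return A list of class `gait_selection`: `selected` (character),
#'   `significant` (character), `decisions` (tibble with per-feature
#'   keep/drop reasons), `cor_matrix` (significant-feature correlations).
#' @export
select_features <- function(stats, table, r_threshold = 0.90, alpha = 0.05) {
  roster_order <- feature_roster()$feature
  sig <- stats[stats$p_value < alpha, , drop = FALSE]
  sig <- sig[order(sig$p_value, match(sig$feature, roster_order)), , drop = FALSE]
  cor_matrix <- NULL
  if (nrow(sig) > 1L) {
    cor_matrix <- suppressWarnings(
      cor(as.matrix(table[, sig$feature]), use = "pairwise.complete.obs")
    )
  }
  accepted <- character(0)
  decisions <- vector("list", nrow(sig))
  for (i in seq_len(nrow(sig))) {
    f <- sig$feature[i]
    conflict <- NULL
    if (length(accepted) > 0L && !is.null(cor_matrix)) {
      r <- abs(cor_matrix[f, accepted])
      r[is.na(r)] <- 0
      if (any(r > r_threshold)) conflict <- accepted[which.max(r)]
    }
    if (is.null(conflict)) {
      accepted <- c(accepted, f)
      decisions[[i]] <- tibble(
        feature = f, p_value = sig$p_value[i], kept = TRUE,
        reason = "significant, not redundant"
      )
    } else {
      decisions[[i]] <- tibble(
        feature = f, p_value = sig$p_value[i], kept = FALSE,
        reason = paste0("|r| > ", r_threshold, " with ", conflict)
      )
    }
  }
  structure(
    list(
      selected = accepted,
      significant = sig$feature,
      decisions = list_rbind(decisions),
      cor_matrix = cor_matrix
    ),
    class = "gait_selection"
  )
}

#' @export
print.gait_selection <- function(x, ...) {
  cat(sprintf(
    "<gait_selection> %d significant, %d selected after |r| pruning\n",
    length(x$significant), length(x$selected)
  ))
  if (length(x$selected) > 0L) {
    cat(" ", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare demographics and clinical scores between groups
#'
#' Numeric variables are routed through Shapiro-Wilk to a Welch t-test or
#' Mann-Whitney U test, like gait features; gender is compared with a
#' Pearson chi-square test (no continuity correction, matching the classic
#' formula) on the 2 x 2 contingency table.
#'
#' @param meta A tibble with `group` plus demographic columns (any of
#'   `age`, `gender`, `bmi`, `education_years`, `gds`, `mmse`, `moca`).
#' @return A tibble: `variable`, `route`, `statistic`, `p_value`, and a
#'   `warning` column flagging low expected cell counts.
#' @export
compare_demographics <- function(meta) {
  groups <- sort(unique(as.character(meta$group)))
  if (length(groups) != 2L) abort("`group` must have exactly 2 levels.")
  if (min(table(meta$group)) < 1L) abort("Both groups must be non-empty.")
  numeric_vars <- intersect(
    c("age", "bmi", "education_years", "gds", "mmse", "moca"), names(meta)
  )
  out <- tibble(variable = character(), route = character(),
                p_value = numeric(), statistic = numeric(),
                warning = character())
  if (length(numeric_vars) > 0L) {
    out <- compare_groups(meta, features = numeric_vars) |>
      dplyr::rename(variable = "feature") |>
      dplyr::mutate(statistic = NA_real_, warning = NA_character_)
  }
  if ("gender" %in% names(meta)) {
    tab <- table(meta$group, meta$gender)
    warn_msg <- NA_character_
    if (ncol(tab) == 2L) {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 1)) {
        warn_msg <- "expected cell count < 1; chi-square approximation unreliable"
        warn(warn_msg)
      }
      cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
      out <- dplyr::bind_rows(out, tibble(
        variable = "gender", route = "chi_square",
        p_value = cs$p.value, statistic = unname(cs$statistic),
        warning = warn_msg
      ))
    }
  }
  dplyr::relocate(out, "variable", "route", "statistic", "p_value")
}
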