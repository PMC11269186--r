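# Synthetic cohort tables with controlled structure for the statistical
# module; features are stored under roster names so the defaults apply.

null_table <- function(n1 = 30, n2 = 25, n_features = 50, seed = 1) {
  withr::with_seed(seed, {
    feats <- feature_roster()$feature[seq_len(min(n_features, 50))]
    tab <- tibble::as_tibble(
      setNames(as.data.frame(matrix(rnorm((n1 + n2) * length(feats)),
                                    n1 + n2)), feats)
    )
    tab$group <- c(rep("HC", n1), rep("MCI", n2))
    tab$bmi <- rnorm(n1 + n2, 25, 3)
    tab$education_years <- rnorm(n1 + n2, 12, 3)
    tab$gds <- pmax(rnorm(n1 + n2, 2, 1), 0)
    tab
  })
}

test_that("adjusting for a covariate with no true effect is a near no-op", {
  tab <- null_table(seed = 31)
  adj <- ancova_adjust(tab)
  feats <- feature_roster()$feature
  rms_change <- sqrt(mean((as.matrix(adj[, feats]) - as.matrix(tab[, feats]))^2))
  # with independent noise covariates the fitted effects are pure noise,
  # so the RMS change stays well below the feature SD (~1)
  expect_lt(rms_change, 0.5)
})

test_that("adjustment removes a constructed confounder effect", {
  withr::with_seed(32, {
    n <- 200
    tab <- tibble::tibble(
      bmi = rnorm(n, 25, 3),
      education_years = rnorm(n, 12, 3),
      gds = rnorm(n, 2, 1),
      group = rep(c("HC", "MCI"), each = n / 2)
    )
    tab$velocity <- 2 * tab$bmi + rnorm(n, 0, 1)
    adj <- ancova_adjust(tab, features = "velocity")
    expect_lt(abs(cor(adj$velocity, tab$bmi)), 0.05)
    expect_equal(mean(adj$velocity), mean(tab$velocity), tolerance = 1e-9)
  })
})

test_that("a constant covariate triggers a rank-deficiency error naming it", {
  tab <- null_table(seed = 33)
  tab$gds <- 2
  expect_error(ancova_adjust(tab), "gds")
})

test_that("adjustment is idempotent", {
  tab <- null_table(seed = 34)
  once <- ancova_adjust(tab)
  twice <- ancova_adjust(once)
  feats <- feature_roster()$feature
  expect_lt(max(abs(as.matrix(twice[, feats]) - as.matrix(once[, feats]))), 1e-9)
})

test_that("group comparisons route by normality and detect strong effects", {
  withr::with_seed(35, {
    tab <- tibble::tibble(
      velocity = c(rnorm(30, 0, 1), rnorm(25, 2, 1)),
      cadence = c(exp(rnorm(30, 0, 1.2)), exp(rnorm(25, 1.2, 1.2))),
      group = c(rep("HC", 30), rep("MCI", 25))
    )
    st <- compare_groups(tab, features = c("velocity", "cadence"))
    expect_identical(st$route[st$feature == "velocity"], "t_test")
    expect_lt(st$p_value[st$feature == "velocity"], 1e-6)
  })
})

test_that("heavy-tailed features are mostly routed to Mann-Whitney", {
  withr::with_seed(36, {
    feats <- feature_roster()$feature[1:20]
    tab <- tibble::as_tibble(setNames(
      as.data.frame(matrix(exp(rnorm(55 * 20, 0, 1.5)), 55)), feats
    ))
    tab$group <- c(rep("HC", 30), rep("MCI", 25))
    st <- compare_groups(tab, features = feats)
    expect_gt(mean(st$route == "mann_whitney"), 0.5)
  })
})

test_that("null features produce ~5% false positives", {
  tab <- null_table(n_features = 50, seed = 37)
  # four independent null tables -> 200 null features in total
  ps <- unlist(lapply(37:40, function(s) compare_groups(null_table(seed = s))$p_value))
  expect_equal(length(ps), 200)
  frac <- mean(ps < 0.05)
  band <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
})

test_that("correlated significant features collapse to the lowest-p member", {
  withr::with_seed(41, {
    n1 <- 30; n2 <- 25
    g <- c(rep(0, n1), rep(1, n2))
    base <- rnorm(n1 + n2) + 1.2 * g
    tab <- null_table(seed = 42)
    # 3-member cluster (pairwise r ~ 0.95) + 2 independent effects
    tab$velocity <- base + rnorm(55, 0, 0.3)
    tab$cadence <- base + rnorm(55, 0, 0.3)
    tab$stride_velocity_me <- base + rnorm(55, 0, 0.3)
    tab$step_length_me <- rnorm(55) + 1.5 * g
    tab$step_width_me <- rnorm(55) + 1.5 * g
    st <- compare_groups(tab)
    sel <- select_features(st, tab)
    cluster <- c("velocity", "cadence", "stride_velocity_me")
    expect_equal(sum(cluster %in% sel$selected), 1)
    kept <- intersect(cluster, sel$selected)
    expect_equal(kept, cluster[which.min(st$p_value[match(cluster, st$feature)])])
    expect_true(all(c("step_length_me", "step_width_me") %in% sel$selected))
    # selected set has no remaining high correlations
    if (length(sel$selected) > 1) {
      cm <- abs(cor(as.matrix(tab[, sel$selected])))
      diag(cm) <- 0
      expect_lte(max(cm), 0.90)
    }
  })
})

test_that("selection handles forced and empty cases", {
  st <- tibble::tibble(
    feature = c("velocity", "cadence"),
    route = "t_test", p_value = c(0.01, 0.02)
  )
  tab <- tibble::tibble(velocity = 1:10, cadence = (1:10) * 2 + 0,
                        group = rep(c("HC", "MCI"), 5))
  sel <- select_features(st, tab) # r = 1 exactly
  expect_identical(sel$selected, "velocity")
  st2 <- dplyr::mutate(st, p_value = c(0.2, 0.9))
  expect_length(select_features(st2, tab)$selected, 0)
})

test_that("demographics tests include the classic chi-square for gender", {
  meta <- tibble::tibble(
    group = c(rep("HC", 30), rep("MCI", 25)),
    gender = c(rep("female", 18), rep("male", 12), rep("female", 19), rep("male", 6)),
    age = c(rnorm(30, 68, 2), rnorm(25, 70, 6))
  )
  out <- suppressWarnings(compare_demographics(meta))
  # closed-form Pearson chi-square on the 2x2 table (18,12 / 19,6)
  tab <- table(meta$group, meta$gender)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  got <- out$statistic[out$variable == "gender"]
  expect_equal(got, chi2, tolerance = 1e-9)

  # identical gender proportions -> p = 1
  meta2 <- tibble::tibble(
    group = rep(c("HC", "MCI"), each = 30),
    gender = rep(rep(c("female", "male"), each = 15), 2)
  )
  out2 <- compare_demographics(meta2)
  expect_equal(out2$p_value[out2$variable == "gender"], 1)

  expect_error(compare_demographics(meta[meta$group == "HC", ]), "2 levels")
})
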