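#' Build a pipeline run configuration
#'
#' Assembles the full set of pipeline parameters with defaults, either
#' programmatically or from a YAML file (`read_run_config()`). Every
#' default that fills a gap the acquisition protocol leaves open (sampling
#' rate, oval geometry, detection thresholds) is an explicit assumption and
#' is persisted with the run outputs.
#'
#' @param seed Integer master seed for the whole run.
#' @param out_dir Output directory for run artifacts.
#' @param simulate `NULL` to read real data via `manifest`, or a list with
#'   `n_hc`, `n_mci`, `path` for a synthetic cohort.
#' @param manifest Path to a cohort manifest CSV (when not simulating).
#' @param filter,events,selection,classify Stage parameter lists; see
#'   defaults in the function body.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "gaitmci_run",
                       simulate = list(n_hc = 6, n_mci = 6, path = "oval"),
                       manifest = NULL,
                       filter = list(order = 6L, cutoff_hz = 3.0),
                       events = list(min_peak_distance_s = 0.3, min_prominence_m = 0.05),
                       selection = list(alpha = 0.05, r_threshold = 0.90),
                       classify = list(models = "random_forest")) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir, simulate = simulate,
    manifest = manifest,
    filter = utils::modifyList(list(order = 6L, cutoff_hz = 3.0), filter %||% list()),
    events = utils::modifyList(
      list(min_peak_distance_s = 0.3, min_prominence_m = 0.05), events %||% list()
    ),
    selection = utils::modifyList(
      list(alpha = 0.05, r_threshold = 0.90), selection %||% list()
    ),
    classify = utils::modifyList(list(models = "random_forest"), classify %||% list())
  )
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any subset of the `run_config()` fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' Run the full screening pipeline
#'
#' Executes the stages in order: simulate (or load) recordings, low-pass
#' filter, extract the 50-feature roster, confounder-adjust and select
#' features, and cross-validate the requested classifiers. Writes
#' `features.csv`, `stats.csv`, `selected.txt`, `report.json`,
#' `config.yaml` and `run.log` into the run directory. All stages are pure
#' functions of (inputs, config, seed), so a rerun with the same config
#' reproduces the outputs.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(fmt, ...))
    cat(line, "\n", sep = "")
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      logf(name, "FAILED: %s", conditionMessage(e))
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))

  feats <- stage("extract", {
    if (!is.null(config$simulate)) {
      cc <- cohort_config(
        n_hc = config$simulate$n_hc %||% 6,
        n_mci = config$simulate$n_mci %||% 6,
        path = config$simulate$path %||% "oval"
      )
      logf("simulate", "simulating %d HC + %d MCI subjects (%s path)",
           cc$n_hc, cc$n_mci, cc$path)
      simulate_cohort_features(
        cc, seed = config$seed,
        order = config$filter$order, cutoff_hz = config$filter$cutoff_hz
      )
    } else {
      mf <- read_manifest(config$manifest)
      logf("extract", "extracting features for %d recordings", nrow(mf))
      extract_cohort_features(
        mf, filter_order = config$filter$order, cutoff_hz = config$filter$cutoff_hz,
        min_peak_distance_s = config$events$min_peak_distance_s,
        min_prominence_m = config$events$min_prominence_m
      )
    }
  })
  readr::write_csv(feats, file.path(config$out_dir, "features.csv"), progress = FALSE)
  logf("extract", "wrote features.csv (%d x %d)", nrow(feats), ncol(feats))

  stats_out <- stage("stats", {
    adj <- ancova_adjust(feats)
    st <- compare_groups(adj)
    sel <- select_features(st, adj,
                           r_threshold = config$selection$r_threshold,
                           alpha = config$selection$alpha)
    logf("stats", "%d significant, %d selected features",
         length(sel$significant), length(sel$selected))
    list(adjusted = adj, stats = st, selection = sel)
  })
  readr::write_csv(stats_out$stats, file.path(config$out_dir, "stats.csv"),
                   progress = FALSE)
  writeLines(stats_out$selection$selected,
             file.path(config$out_dir, "selected.txt"))

  reports <- stage("classify", {
    map(config$classify$models, function(m) {
      rep <- run_cv_experiment(
        stats_out$adjusted,
        classifier_spec(m, seed = config$seed),
        adjust_covariates = FALSE, # already adjusted above
        alpha = config$selection$alpha,
        r_threshold = config$selection$r_threshold
      )
      logf("classify", "%s pooled accuracy %.1f%%", m, rep$metrics$accuracy)
      rep
    })
  })
  report_json <- map(reports, function(r) {
    list(
      classifier = r$kind, seed = r$seed, n = r$n, positive = r$positive,
      confusion = as.list(r$confusion),
      metrics = as.list(r$metrics),
      folds = map(r$folds, function(fi) {
        list(fold = fi$fold, best_params = fi$best_params,
             n_features = length(fi$features), features = fi$features)
      })
    )
  })
  jsonlite::write_json(report_json, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("done", "all artifacts written to %s", config$out_dir)
  invisible(config$out_dir)
}
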