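#' End-to-end run configuration
#'
#' Bundles every stage's settings and seeds. A single global seed expands
#' deterministically to per-stage seeds (cohort, embedding, clustering,
#' classification, regression = seed + 0..4).
#'
#' @param cohort A [cohort_config()] describing the simulated cohort, or
#'   a directory containing detection JSONs plus `ratings.csv` and
#'   `cbarq.csv` (as written by [write_cohort()]).
#' @param min_coverage Quality-gate threshold in (0, 1].
#' @param smooth_window Moving-average width, frames.
#' @param target_fps Standardized frame rate.
#' @param grid Autoencoder hyperparameter grid (see
#'   [train_autoencoder()]).
#' @param k_max Largest candidate cluster count.
#' @param budget Pipeline-search budget per supervised task.
#' @param include_negative Include '-'-labeled trials in the supervised
#'   stages (excluded by default; the negative class is typically too
#'   small).
#' @param seed Global integer seed.
#' @param out_dir Optional directory for stage artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       min_coverage = 0.80, smooth_window = 5,
                       target_fps = 24,
                       grid = list(n_filters = c(4, 8),
                                   learning_rate = 1e-3),
                       k_max = 8, budget = 200,
                       include_negative = FALSE,
                       seed = 1, out_dir = NULL) {
  if (!(min_coverage > 0 && min_coverage <= 1))
    stop("min_coverage must be in (0, 1]")
  stopifnot(smooth_window >= 1, target_fps > 0, k_max >= 3, budget >= 1)
  structure(list(cohort = cohort, min_coverage = min_coverage,
                 smooth_window = smooth_window, target_fps = target_fps,
                 grid = grid, k_max = k_max, budget = budget,
                 include_negative = include_negative,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

read_cohort_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  files <- files[!grepl("manifest", files)]
  trials <- lapply(files, read_detections)
  names(trials) <- vapply(trials, function(t) t$trial_id, character(1))
  ratings <- utils::read.csv(file.path(dir, "ratings.csv"),
                             colClasses = "character")
  cbarq <- utils::read.csv(file.path(dir, "cbarq.csv"))
  list(trials = trials, ratings = ratings, cbarq = cbarq)
}

#' Run the whole digital assessment pipeline
#'
#' Executes, in order: simulate (or load) the cohort; quality-gate, fill,
#' smooth, resample and truncate the detections; train the autoencoder
#' and embed each trial into the movement space; screen outliers, select
#' k by the elbow rule and cluster; aggregate expert scores and compute
#' agreement statistics; compare C-BARQ categories between the two
#' clusters; and fit the supervised score classifier and per-category
#' C-BARQ regressors on the movement embeddings. Idempotent for a fixed
#' configuration.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report` (a list; see fields in the
#'   source). If `config$out_dir` is set, stage artifacts are written
#'   there as CSV/JSON.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # -- simulate / load ------------------------------------------------------
  inp <- stage("simulate", {
    if (inherits(config$cohort, "cohort_config")) {
      cc <- config$cohort
      cc$seed <- seed
      simulate_cohort(cc)
    } else read_cohort_dir(config$cohort)
  })
  n_raw <- length(inp$trials)

  # -- preprocess -----------------------------------------------------------
  prep <- stage("preprocess",
                preprocess_cohort(inp$trials,
                                  min_coverage = config$min_coverage,
                                  smooth_window = config$smooth_window,
                                  target_fps = config$target_fps))
  dataset <- prep$dataset

  # -- embed ----------------------------------------------------------------
  trained <- stage("embed",
                   train_autoencoder(dataset, grid = config$grid,
                                     seed = seed + 1L))
  Z <- stage("embed", encode(trained$model, dataset))

  # -- cluster --------------------------------------------------------------
  clus <- stage("cluster",
                cluster_trials(Z, k_max = config$k_max, seed = seed + 2L))

  # -- validate -------------------------------------------------------------
  votes <- stage("validate", collapse_and_vote(inp$ratings))
  agreement <- stage("validate", agreement_report(
    votes[, c("rater1", "rater2", "rater3")]))
  labels <- stats::setNames(votes$majority, votes$trial_id)
  clustered_ids <- names(clus$assignments)
  xt <- stage("validate",
              crosstab(clus$assignments, labels[clustered_ids]))
  cbarq_cmp <- NULL
  if (clus$k_selected == 2)
    cbarq_cmp <- stage("validate",
                       compare_clusters_cbarq(inp$cbarq, clus$assignments))

  # -- supervised models ----------------------------------------------------
  keep_lab <- labels[clustered_ids]
  ok <- !is.na(keep_lab) & (config$include_negative | keep_lab != "-")
  ids_sup <- clustered_ids[ok]
  Xsup <- Z[ids_sup, , drop = FALSE]
  cls_res <- stage("train classifier", pipeline_search(
    Xsup, labels[ids_sup],
    search_config("classification", budget = config$budget,
                  seed = seed + 3L)))
  reg_res <- stage("train regressors", {
    lapply(stats::setNames(nm = cbarq_categories()), function(cat) {
      yv <- inp$cbarq[[cat]][match(ids_sup, inp$cbarq$trial_id)]
      pipeline_search(Xsup, yv,
                      search_config("regression", budget = config$budget,
                                    seed = seed + 4L))
    })
  })
  reg_table <- do.call(rbind, lapply(cbarq_categories(), function(cat) {
    r <- reg_res[[cat]]$report
    data.frame(category = cat, mae = r$mae, mse = r$mse, r2 = r$r2)
  }))

  report <- structure(list(
    n_raw = n_raw,
    quality_report = prep$report,
    post_fill_coverage = prep$post_fill_coverage,
    m_time = dataset$m_time,
    embedding_grid = trained$grid_results,
    k_selected = clus$k_selected,
    inertia_curve = clus$inertia_curve,
    excluded_outliers = clus$excluded_outliers,
    assignments = clus$assignments,
    crosstab = xt,
    agreement = agreement,
    cbarq_comparison = cbarq_cmp,
    classifier = cls_res$report,
    classifier_pipeline = cls_res$best_pipeline,
    regression = reg_table,
    n_supervised = length(ids_sup),
    seed = seed), class = "run_report")

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(prep$report, file.path(d, "exclusions.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(trial_id = names(clus$assignments),
                                cluster = clus$assignments),
                     file.path(d, "clusters.csv"), row.names = FALSE)
    utils::write.csv(clus$inertia_curve, file.path(d, "inertia.csv"),
                     row.names = FALSE)
    if (!is.null(cbarq_cmp))
      utils::write.csv(cbarq_cmp, file.path(d, "cbarq_comparison.csv"),
                       row.names = FALSE)
    utils::write.csv(reg_table, file.path(d, "regression_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(d, "report.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  report
}

# plain-list view used for serialization and byte-identity checks
report_to_json <- function(report) {
  r <- unclass(report)
  r$crosstab <- as.data.frame.matrix(r$crosstab)
  r$assignments <- as.list(r$assignments)
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  trials: ", x$n_raw, " raw -> ",
      sum(x$quality_report$retained), " retained -> ",
      length(x$assignments), " clustered\n", sep = "")
  cat("  k selected:", x$k_selected, "\n")
  cat(sprintf("  agreement: Po = %.3f, free-marginal kappa = %.2f\n",
              x$agreement$percent_agreement, x$agreement$kappa))
  cat(sprintf("  classifier: accuracy %.3f (precision %.3f, recall %.3f, F1 %.3f)\n",
              x$classifier$accuracy, x$classifier$precision,
              x$classifier$recall, x$classifier$f1))
  invisible(x)
}
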