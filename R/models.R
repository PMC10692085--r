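#' Configuration for the budgeted pipeline search
#'
#' @param task `"classification"` or `"regression"`.
#' @param budget Maximum number of distinct pipelines evaluated (the
#'   default cap is 10,000; typical runs use a few hundred).
#' @param cv_folds Stratified cross-validation folds.
#' @param seed Integer seed driving folds, initialization and evolution.
#' @param pop_size Evolutionary population size.
#' @param mutation_rate Per-gene mutation probability.
#' @return An object of class `search_config`.
#' @export
search_config <- function(task = c("classification", "regression"),
                          budget = 10000, cv_folds = 5, seed = 1,
                          pop_size = 20, mutation_rate = 0.3) {
  task <- match.arg(task)
  stopifnot(budget >= 1, cv_folds >= 2, pop_size >= 2,
            mutation_rate > 0, mutation_rate <= 1)
  structure(list(task = task, budget = budget, cv_folds = cv_folds,
                 seed = as.integer(seed), pop_size = pop_size,
                 mutation_rate = mutation_rate),
            class = "search_config")
}

# ---- pipeline component space ---------------------------------------------

pipeline_space <- function(task) {
  list(
    scaler = c("none", "zscore"),
    selector = c("none", "variance", "univariate"),
    n_features = c(8, 16, 32, 64),
    estimator = c("glmnet", "ranger", "knn", "svm"),
    glmnet_alpha = c(0, 0.5, 1),
    glmnet_lambda = c(0.001, 0.01, 0.1),
    ranger_trees = c(100, 300),
    ranger_mtry_frac = c(0.1, 0.33, 0.7),
    knn_k = c(1, 3, 5, 7),
    svm_cost = c(0.1, 1, 10),
    svm_gamma_mult = c(0.5, 1, 2)
  )
}

random_pipeline <- function(space) {
  lapply(space, function(v) v[sample.int(length(v), 1)])
}

mutate_pipeline <- function(pl, space, rate) {
  for (g in names(space)) {
    if (stats::runif(1) < rate)
      pl[[g]] <- space[[g]][sample.int(length(space[[g]]), 1)]
  }
  pl
}

crossover_pipeline <- function(a, b) {
  pick <- stats::runif(length(a)) < 0.5
  out <- a
  out[pick] <- b[pick]
  out
}

pipeline_signature <- function(pl)
  paste(vapply(pl, as.character, character(1)), collapse = "|")

# ---- fitting one pipeline on one split ------------------------------------

fit_predict_pipeline <- function(pl, X_tr, y_tr, X_te, task, seed) {
  # scaler
  if (pl$scaler == "zscore") {
    mu <- colMeans(X_tr)
    sd <- apply(X_tr, 2, stats::sd)
    sd[sd < 1e-12] <- 1
    X_tr <- sweep(sweep(X_tr, 2, mu), 2, sd, "/")
    X_te <- sweep(sweep(X_te, 2, mu), 2, sd, "/")
  }
  # selector
  p <- ncol(X_tr)
  q <- min(pl$n_features, p)
  if (pl$selector == "variance") {
    keep <- order(apply(X_tr, 2, stats::var), decreasing = TRUE)[seq_len(q)]
    X_tr <- X_tr[, keep, drop = FALSE]; X_te <- X_te[, keep, drop = FALSE]
  } else if (pl$selector == "univariate") {
    ynum <- if (task == "classification") as.numeric(factor(y_tr)) else y_tr
    sc <- abs(suppressWarnings(apply(X_tr, 2, function(col)
      stats::cor(col, ynum))))
    sc[is.na(sc)] <- 0
    keep <- order(sc, decreasing = TRUE)[seq_len(q)]
    X_tr <- X_tr[, keep, drop = FALSE]; X_te <- X_te[, keep, drop = FALSE]
  }
  cls <- task == "classification"
  if (cls) y_tr <- factor(y_tr)
  switch(pl$estimator,
    glmnet = {
      fam <- if (cls) "binomial" else "gaussian"
      # small CV folds trip glmnet's class-size advisory; harmless here
      fit <- suppressWarnings(
        glmnet::glmnet(X_tr, y_tr, family = fam,
                       alpha = pl$glmnet_alpha,
                       lambda = pl$glmnet_lambda))
      if (cls) {
        lp <- as.numeric(stats::predict(fit, newx = X_te, type = "link"))
        levels(y_tr)[1 + as.integer(lp > 0)]
      } else
        as.numeric(stats::predict(fit, newx = X_te))
    },
    ranger = {
      df_tr <- data.frame(X_tr); df_tr$.y <- y_tr
      mtry <- max(1L, floor(pl$ranger_mtry_frac * ncol(X_tr)))
      fit <- ranger::ranger(.y ~ ., data = df_tr,
                            num.trees = pl$ranger_trees, mtry = mtry,
                            seed = seed, num.threads = 1)
      pr <- stats::predict(fit, data.frame(X_te))$predictions
      if (cls) as.character(pr) else as.numeric(pr)
    },
    knn = {
      k <- min(pl$knn_k, nrow(X_tr))
      if (cls) {
        as.character(class::knn(X_tr, X_te, y_tr, k = k, use.all = TRUE))
      } else {
        d2 <- outer(rowSums(X_te^2), rowSums(X_tr^2), "+") -
          2 * X_te %*% t(X_tr)
        apply(d2, 1, function(row)
          mean(y_tr[order(row)[seq_len(k)]]))
      }
    },
    svm = {
      gam <- pl$svm_gamma_mult / ncol(X_tr)
      fit <- e1071::svm(X_tr, y_tr, kernel = "radial", cost = pl$svm_cost,
                        gamma = gam, scale = FALSE,
                        type = if (cls) "C-classification"
                               else "eps-regression")
      pr <- stats::predict(fit, X_te)
      if (cls) as.character(pr) else as.numeric(pr)
    })
}

stratified_folds <- function(y, k, task) {
  n <- length(y)
  fold <- integer(n)
  strata <- if (task == "classification") factor(y) else {
    # consecutive response-ordered bins of size k spread y across folds
    ceiling(rank(y, ties.method = "first") / k)
  }
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

cv_evaluate <- function(pl, X, y, fold, task, seed) {
  k <- max(fold)
  oof <- if (task == "classification") character(length(y))
         else numeric(length(y))
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    if (task == "classification" && length(unique(y[tr])) < 2) return(NULL)
    oof[te] <- fit_predict_pipeline(pl, X[tr, , drop = FALSE], y[tr],
                                    X[te, , drop = FALSE], task, seed)
  }
  score <- if (task == "classification") mean(oof == y)
           else -mean((oof - y)^2)
  list(score = score, oof = oof)
}

#' Budgeted evolutionary search over machine-learning pipelines
#'
#' An automated-ML search in the TPOT spirit: candidate pipelines are
#' \{optional scaler\} -> \{optional variance / univariate feature
#' selector\} -> \{estimator in a fixed set of linear (elastic-net),
#' tree-ensemble (random forest), k-nearest-neighbour and RBF-kernel
#' models with their hyperparameters\}. A seeded evolutionary loop
#' (tournament selection, uniform crossover, per-gene mutation, elitism)
#' evaluates up to `config$budget` distinct pipelines by stratified
#' cross-validated score (accuracy, or negative MSE for regression) and
#' returns the best. Fully reproducible given the config seed.
#'
#' @param X Numeric feature matrix (rows = trials).
#' @param y Targets: labels for classification, numeric for regression.
#' @param config A [search_config()].
#' @return List with `best_pipeline`, `best_score`, `report` (the metric
#'   set from pooled out-of-fold predictions of the winner: accuracy /
#'   precision / recall / f1, or mae / mse / r2), `oof` (out-of-fold
#'   predictions), `log` (one row per evaluated pipeline) and `n_evaluated`.
#' @export
pipeline_search <- function(X, y, config) {
  stopifnot(inherits(config, "search_config"))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows must align with y")
  if (nrow(X) < 10) stop("need at least 10 samples for cross-validation")
  task <- config$task
  if (task == "classification" && length(unique(y)) < 2)
    stop("classification needs at least 2 classes in y")
  set.seed(config$seed)
  fold <- stratified_folds(y, config$cv_folds, task)
  space <- pipeline_space(task)

  cache <- new.env(parent = emptyenv())
  log <- NULL
  n_eval <- 0
  evaluate <- function(pl) {
    sig <- pipeline_signature(pl)
    if (!is.null(cache[[sig]])) return(cache[[sig]])
    if (n_eval >= config$budget) return(NULL)
    res <- cv_evaluate(pl, X, y, fold, task, seed = config$seed)
    if (is.null(res)) res <- list(score = -Inf, oof = NULL)
    n_eval <<- n_eval + 1
    log <<- rbind(log, data.frame(eval = n_eval, signature = sig,
                                  estimator = pl$estimator,
                                  score = res$score))
    res$pipeline <- pl
    cache[[sig]] <- res
    res
  }

  pop_size <- min(config$pop_size, config$budget)
  population <- list()
  best <- NULL
  while (length(population) < pop_size && n_eval < config$budget) {
    pl <- random_pipeline(space)
    res <- evaluate(pl)
    if (is.null(res)) break
    population <- c(population, list(res))
    if (is.null(best) || res$score > best$score) best <- res
  }
  tournament <- function() {
    idx <- sample.int(length(population), min(3, length(population)))
    scores <- vapply(population[idx], `[[`, numeric(1), "score")
    population[[idx[which.max(scores)]]]$pipeline
  }
  attempts <- 0
  max_attempts <- 50 * config$budget  # duplicates hit the cache for free
  while (n_eval < config$budget && attempts < max_attempts) {
    attempts <- attempts + 1
    child <- if (stats::runif(1) < 0.5 && length(population) >= 2)
      crossover_pipeline(tournament(), tournament()) else tournament()
    child <- mutate_pipeline(child, space, config$mutation_rate)
    res <- evaluate(child)
    if (is.null(res)) break
    # steady-state replacement of the current worst
    scores <- vapply(population, `[[`, numeric(1), "score")
    worst <- which.min(scores)
    if (res$score > scores[worst]) population[[worst]] <- res
    if (res$score > best$score) best <- res
  }

  report <- if (task == "classification")
    evaluate_classifier(y, best$oof)
  else
    evaluate_regressor(y, best$oof)
  list(best_pipeline = best$pipeline, best_score = best$score,
       report = report, oof = best$oof, log = log, n_evaluated = n_eval,
       folds = fold)
}
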