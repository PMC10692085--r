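# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# short-trial arena used wherever full 40 s trials are unnecessary
small_arena <- function(duration = 10, jitter = 1)
  arena_spec(duration = duration, duration_jitter = jitter)

small_cohort_config <- function(seed, n_trials = 12,
                                duration = 10, jitter = 1)
  cohort_config(n_trials = n_trials,
                style_proportions = c(towards = 0.5, neutral = 0.5,
                                      away = 0),
                arena = small_arena(duration, jitter), seed = seed)

# gap-free detections for hand-built paths (no corruption)
perfect_trial <- function(dog, fps = 24, trial_id = "t",
                          person = matrix(2.35, nrow(dog), 2)) {
  corrupt_detections(list(dog = dog, person = person, fps = fps),
                     miss_rate = 0, noise_sd = 0, seed = 1,
                     trial_id = trial_id)
}

# the default full-scale cohort (n = 46, 28 neutral / 18 towards) with
# its preprocessed dataset, trained autoencoder and movement embeddings
fx_cohort46 <- function() memo("cohort46", function() {
  co <- simulate_cohort(cohort_config(seed = 42))
  pp <- preprocess_cohort(co$trials)
  tr <- train_autoencoder(pp$dataset, seed = 7)
  Z <- encode(tr$model, pp$dataset)
  list(co = co, pp = pp, trained = tr, Z = Z,
       truth = stats::setNames(co$truth$style, co$truth$trial_id))
})

# 20 reduced-scale cohorts (15 s trials, 20 dogs) with embeddings,
# reused by the embedding-separation and cluster-recovery properties
fx_small_embeddings <- function() memo("small_embeddings", function() {
  lapply(1:20, function(s) {
    co <- simulate_cohort(small_cohort_config(seed = s, n_trials = 20,
                                              duration = 15))
    pp <- preprocess_cohort(co$trials)
    tr <- train_autoencoder(pp$dataset,
                            grid = list(n_filters = 4, epochs = 40,
                                        patience = 10),
                            seed = s + 500)
    Z <- encode(tr$model, pp$dataset)
    list(Z = Z, truth = stats::setNames(co$truth$style, co$truth$trial_id))
  })
})

# adjusted Rand index of k = 2 recovery of the true styles, per seed
fx_recovery_aris <- function() memo("recovery_aris", function() {
  vapply(fx_small_embeddings(), function(f) {
    fit <- kmeans_fit(f$Z, 2, seed = 11)
    mclust::adjustedRandIndex(f$truth[names(fit$assignments)],
                              fit$assignments)
  }, numeric(1))
})

# regression on the noiseless excitability signal from its own covariates
fx_noiseless_exc <- function() memo("noiseless_exc", function() {
  coup <- default_cbarq_coupling()
  coup$EXC$noise_sd <- 0
  co <- simulate_cohort(cohort_config(seed = 5, cbarq_coupling = coup))
  X <- as.matrix(co$truth[, c("mean_speed", "frac_near_tp")])
  y <- co$cbarq$EXC
  pipeline_search(X, y, search_config("regression", budget = 40, seed = 3))
})

# worst |normal - exact| two-sided p over every tie-free rank arrangement
# at n1 = n2 = 6 (U depends on ranks only, so this is exhaustive)
fx_mw_worst_gap <- function() memo("mw_worst_gap", function() {
  combos <- utils::combn(12, 6)
  worst <- 0
  for (j in seq_len(ncol(combos))) {
    x <- combos[, j]
    mw <- mann_whitney(x, setdiff(1:12, x))
    worst <- max(worst, abs(mw$p - mw$p_exact))
  }
  worst
})

# independent confusion-matrix oracle for classification metrics
oracle_classifier_metrics <- function(y_true, y_pred) {
  lev <- sort(unique(y_true))
  tab <- table(factor(y_true, lev), factor(y_pred, lev))
  prec <- rec <- f1 <- numeric(length(lev))
  for (i in seq_along(lev)) {
    tp <- tab[i, i]
    prec[i] <- if (sum(tab[, i]) > 0) tp / sum(tab[, i]) else 0
    rec[i] <- if (sum(tab[i, ]) > 0) tp / sum(tab[i, ]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(accuracy = sum(diag(tab)) / sum(tab), precision = mean(prec),
       recall = mean(rec), f1 = mean(f1))
}

# exhaustive-partition k-means oracle (minimum inertia over assignments)
brute_force_inertia <- function(Z, k) {
  n <- nrow(Z)
  assign_grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(assign_grid))) {
    a <- assign_grid[r, ]
    if (length(unique(a)) < k) next
    inertia <- 0
    for (j in seq_len(k)) {
      pts <- Z[a == j, , drop = FALSE]
      ctr <- colMeans(pts)
      inertia <- inertia + sum(sweep(pts, 2, ctr)^2)
    }
    if (inertia < best) best <- inertia
  }
  best
}
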