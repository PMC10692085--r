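test_that("k-means handles the degenerate and well-separated regimes", {
  set.seed(2)
  Z <- matrix(rnorm(12), 6, 2)
  rownames(Z) <- letters[1:6]
  full <- kmeans_fit(Z, k = 6, seed = 1)
  expect_equal(full$inertia, 0)
  expect_equal(sort(unname(full$assignments)), 1:6)
  blobs <- rbind(matrix(rnorm(20, -10, 0.1), 10, 2),
                 matrix(rnorm(20, 10, 0.1), 10, 2))
  fit <- kmeans_fit(blobs, 2, seed = 3)
  expect_equal(mclust::adjustedRandIndex(fit$assignments,
                                         rep(1:2, each = 10)), 1)
  expect_error(kmeans_fit(Z, 0), "k must be")
  expect_error(kmeans_fit(Z, 7), "k must be")
})

test_that("k-means recovers the known optimum on the 1-D benchmark", {
  Z <- matrix(c(0, 1, 2, 3, 10, 11, 12, 13), ncol = 1)
  fit <- kmeans_fit(Z, 2, seed = 1)
  expect_equal(fit$inertia, 10.0)
  expect_equal(length(unique(fit$assignments[1:4])), 1)
  expect_equal(length(unique(fit$assignments[5:8])), 1)
})

test_that("k-means attains the exhaustive-partition optimum on small n", {
  set.seed(8)
  cases <- list(list(n = 7, k = 2), list(n = 8, k = 3), list(n = 10, k = 3),
                list(n = 9, k = 2))
  for (cs in cases) {
    Z <- matrix(rnorm(cs$n * 2), cs$n, 2)
    fit <- kmeans_fit(Z, cs$k, seed = 4, n_init = 20)
    expect_equal(fit$inertia, brute_force_inertia(Z, cs$k),
                 tolerance = 1e-8)
  }
})

test_that("k-means matches the reference implementation's optimum", {
  set.seed(10)
  Z <- matrix(rnorm(60 * 3), 60, 3)
  ours <- kmeans_fit(Z, 3, seed = 2, n_init = 20)
  ref <- stats::kmeans(Z, 3, nstart = 20, iter.max = 100)
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("inertia does not increase with k", {
  set.seed(11)
  Z <- matrix(rnorm(40 * 4), 40, 4)
  curve <- inertia_curve(Z, k_max = 8, seed = 5)
  expect_true(all(diff(curve$inertia) <= 1e-8))
})

test_that("the elbow detector finds the max-chord-distance knee", {
  expect_equal(elbow_select(c(100, 40, 35, 33, 32)), 2)
  expect_equal(elbow_select(c(100, 75, 50, 25)), 1)  # linear: no elbow
  # invariant under affine rescaling of the inertia axis
  curve <- c(90, 30, 22, 18, 16, 15)
  for (a in c(0.01, 1, 250)) for (b in c(-5, 0, 100))
    expect_equal(elbow_select(a * curve + b), elbow_select(curve))
  expect_warning(elbow_select(c(100, 40, 45, 33)), "not non-increasing")
})

test_that("the MAD rule flags the injected extreme point only", {
  set.seed(1)
  Z <- matrix(rnorm(92), 46, 2)
  rownames(Z) <- sprintf("t%02d", 1:46)
  expect_length(detect_outliers(Z), 0)
  Zo <- rbind(Z, far = c(100, 100))
  expect_identical(detect_outliers(Zo), "far")
  expect_length(detect_outliers(matrix(1, 8, 2)), 0)  # identical points
  expect_error(detect_outliers(Z[1:3, ]), "at least 5")
})

test_that("cross-tabulation reproduces margins and conserves trials", {
  ids <- sprintf("d%02d", 1:46)
  labels <- stats::setNames(rep(c("0", "+"), c(28, 18)), ids)
  assign <- stats::setNames(
    c(rep(1L, 21), rep(2L, 7), rep(1L, 5), rep(2L, 13)), ids)
  tab <- crosstab(assign, labels)
  expect_equal(unname(tab["0", c("1", "2")]), c(21, 7))
  expect_equal(unname(tab["+", c("1", "2")]), c(5, 13))
  expect_equal(unname(tab["Sum", c("1", "2", "Sum")]), c(26, 20, 46))
  expect_equal(unname(tab[c("0", "+"), "Sum"]), c(28, 18))
  # identical partitions give a diagonal table
  same <- stats::setNames(rep(1:2, 5), sprintf("x%d", 1:10))
  tab2 <- crosstab(same, stats::setNames(c("a", "b")[same], names(same)))
  expect_equal(unname(tab2["a", "2"]), 0)
  expect_equal(unname(tab2["b", "1"]), 0)
  expect_error(crosstab(assign, labels[-1]), "same trial ids")
})

test_that("the 2-D projection is a deterministic unit-square layout", {
  set.seed(13)
  Z <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 5, 0.3), 20, 2))
  rownames(Z) <- sprintf("p%02d", 1:40)
  Y <- project_2d(Z, seed = 3)
  expect_true(all(Y >= 0 & Y <= 1))
  expect_equal(unname(apply(Y, 2, min)), c(0, 0))
  expect_equal(unname(apply(Y, 2, max)), c(1, 1))
  expect_identical(Y, project_2d(Z, seed = 3))
  expect_identical(rownames(Y), rownames(Z))
  # well-separated groups stay separated in the plane
  g <- rep(1:2, each = 20)
  km <- kmeans_fit(Y, 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(km$assignments, g), 1)
  expect_error(project_2d(Z[1:4, ]), "at least 5")
})

test_that("clusters recover the coping styles across seeds", {
  aris <- fx_recovery_aris()
  expect_gte(sum(aris >= 0.6), 18)
})

test_that("the full clustering stage reports a coherent result", {
  f <- fx_small_embeddings()[[1]]
  res <- cluster_trials(f$Z, k_max = 6, seed = 4)
  expect_s3_class(res, "clustering_result")
  expect_true(all(names(res$assignments) %in% rownames(f$Z)))
  expect_equal(length(res$assignments) + length(res$excluded_outliers),
               nrow(f$Z))
  expect_true(all(diff(res$inertia_curve$inertia) <= 1e-8))
})
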