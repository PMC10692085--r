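test_that("score collapse groups sign and majority voting follows it", {
  df <- data.frame(rater1 = c(1, 0, 1, -2), rater2 = c(2, 0, 0, -1),
                   rater3 = c(0, 0, -1, 2))
  v <- collapse_and_vote(df)
  expect_identical(v$rater1, c("+", "0", "+", "-"))
  expect_identical(v$majority, c("+", "0", NA, "-"))
  expect_identical(v$tie, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(collapse_and_vote(data.frame(rater1 = 3, rater2 = 0,
                                            rater3 = 0)),
               "outside")
})

test_that("majority voting is invariant under rater permutation", {
  set.seed(14)
  for (i in 1:50) {
    raw <- sample(-2:2, 3, replace = TRUE)
    perm <- sample(raw)
    v1 <- collapse_and_vote(data.frame(rater1 = raw[1], rater2 = raw[2],
                                       rater3 = raw[3]))
    v2 <- collapse_and_vote(data.frame(rater1 = perm[1], rater2 = perm[2],
                                       rater3 = perm[3]))
    expect_identical(v1$majority, v2$majority)
  }
})

test_that("pairwise observed agreement counts agreeing rater pairs", {
  expect_equal(percent_agreement(matrix("0", 10, 3)), 1.0)
  expect_equal(percent_agreement(rbind(c("+", "+", "0"))), 1 / 3)
  # 41 unanimous + 12 two-one splits over 53 subjects -> 45/53
  m <- rbind(matrix("0", 41, 3),
             matrix(rep(c("+", "+", "0"), 12), 12, 3, byrow = TRUE))
  expect_equal(percent_agreement(m), 45 / 53)
  expect_error(percent_agreement(rbind(c("+", NA, "0"))), "complete")
  # invariant under category relabeling
  set.seed(3)
  m2 <- matrix(sample(c("-", "0", "+"), 60, TRUE), 20, 3)
  relab <- c("-" = "b", "0" = "c", "+" = "a")
  expect_equal(percent_agreement(m2),
               percent_agreement(matrix(relab[m2], 20, 3)))
})

test_that("free-marginal kappa is the affine chance correction", {
  expect_equal(free_marginal_kappa(1), 1)
  expect_equal(free_marginal_kappa(1 / 3, 3), 0)
  expect_equal(round(free_marginal_kappa(45 / 53, 3), 2), 0.77)
  # strictly increasing affine in Po
  po <- seq(0, 1, 0.1)
  k <- vapply(po, free_marginal_kappa, numeric(1))
  expect_true(all(diff(k) > 0))
  expect_equal(diff(k), rep(diff(k)[1], 10))
  expect_equal(free_marginal_kappa(0, 3), -0.5)
})

test_that("Mann-Whitney U matches exact enumeration on disjoint groups", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_exact, 0.1)  # 2 of the 20 labelings are as extreme
  expect_equal(mw$U1 + mw$U2, 9)
})

test_that("fully tied groups give the symmetric null statistic", {
  mw <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_equal(mw$U, 4 * 5 / 2)
  expect_equal(mw$z, 0)
  expect_equal(mw$p, 1)
})

test_that("U and its complement always sum to n1 * n2", {
  set.seed(9)
  for (i in 1:50) {
    x <- rnorm(sample(2:8, 1))
    y <- sample(0:3, sample(2:8, 1), replace = TRUE)
    mw <- mann_whitney(x, y)
    expect_equal(mw$U1 + mw$U2, length(x) * length(y))
    expect_equal(mw$U, min(mw$U1, mw$U2))
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("the tie-corrected z agrees with the standard implementation", {
  set.seed(21)
  for (i in 1:25) {
    x <- sample(0:4, 12, replace = TRUE)
    y <- sample(0:4, 15, replace = TRUE)
    mw <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(mw$p, ref$p.value, tolerance = 1e-10)
    expect_equal(max(mw$U1, mw$U2), max(ref$statistic,
                                        length(x) * length(y) - ref$statistic))
  }
})

test_that("normal approximation tracks the exact null at n1 = n2 = 6", {
  expect_lt(fx_mw_worst_gap(), 0.02)
})

test_that("cluster C-BARQ comparison emits one row per category", {
  co <- simulate_cohort(small_cohort_config(seed = 12, n_trials = 16,
                                            duration = 4))
  assign <- stats::setNames(
    ifelse(co$truth$style == "towards", 1L, 2L), co$truth$trial_id)
  out <- compare_clusters_cbarq(co$cbarq, assign)
  expect_equal(nrow(out), 8)
  expect_identical(out$category, cbarq_categories())
  expect_true(all(out$p >= out$p * 0 & out$p <= 1))
  expect_true(all(out$p_holm >= out$p))
  three <- assign
  three[1] <- 3L
  expect_error(compare_clusters_cbarq(co$cbarq, three), "exactly 2 clusters")
})

test_that("no category is spuriously significant under the null", {
  # both clusters drawn from the same distribution: one fixed-seed run
  styles <- rep("neutral", 46)
  cov <- data.frame(mean_speed = rnorm(46, 1, 0.1) * 0 + 1,
                    frac_near_tp = rep(0.1, 46))
  set.seed(33)
  cb <- generate_cbarq(styles, cov)
  assign <- stats::setNames(rep(c(1L, 2L), 23), cb$trial_id)
  out <- compare_clusters_cbarq(cb, assign)
  expect_true(all(out$p > 0.001))
})

test_that("style-coupled SDF separates the clusters with power", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    styles <- c(rep("neutral", 28), rep("towards", 18))
    cov <- data.frame(mean_speed = ifelse(styles == "towards", 2.1, 0.75),
                      frac_near_tp = ifelse(styles == "towards", 0.9, 0.05))
    cb <- generate_cbarq(styles, cov)
    assign <- stats::setNames(ifelse(styles == "towards", 2L, 1L),
                              cb$trial_id)
    out <- compare_clusters_cbarq(cb, assign)
    out$p[out$category == "SDF"] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 18)
})
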