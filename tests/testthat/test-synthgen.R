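test_that("trajectories stay inside the arena and the stranger stays put", {
  for (style in coping_styles()) {
    p <- generate_trajectory(style, seed = 99, n_frames = 600)
    expect_true(all(p$dog >= 0 & p$dog <= 4.7))
    expect_true(all(p$person[, 1] == 2.35 & p$person[, 2] == 2.35))
  }
  expect_error(generate_trajectory("sideways"), "invalid coping style")
})

test_that("trajectory generation is reproducible given the seed", {
  a <- generate_trajectory("neutral", seed = 7, n_frames = 200)
  b <- generate_trajectory("neutral", seed = 7, n_frames = 200)
  expect_identical(a, b)
})

test_that("mean stranger distance orders towards < neutral < away", {
  mean_dist <- function(style, seed) {
    p <- generate_trajectory(style, seed = seed, n_frames = 480)
    mean(sqrt(rowSums((p$dog - p$person)^2)))
  }
  ok <- vapply(1:100, function(s) {
    mean_dist("towards", s) < mean_dist("neutral", s) &&
      mean_dist("neutral", s) < mean_dist("away", s)
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("stronger towards-attraction strictly shortens stranger distance", {
  params <- default_motion_params()$towards
  stronger <- params
  stronger$attraction <- params$attraction * 2
  d <- vapply(1:100, function(s) {
    base <- generate_trajectory("towards", params = params, seed = s,
                                n_frames = 480)
    tight <- generate_trajectory("towards", params = stronger, seed = s,
                                 n_frames = 480)
    mean(sqrt(rowSums((tight$dog - tight$person)^2))) <
      mean(sqrt(rowSums((base$dog - base$person)^2)))
  }, logical(1))
  # sign test against p = 1/2
  expect_lt(stats::binom.test(sum(d), 100, alternative = "greater")$p.value,
            0.01)
})

test_that("detection corruption matches its miss rate and noise contract", {
  path <- generate_trajectory("neutral", seed = 3, n_frames = 1000)
  clean <- corrupt_detections(path, miss_rate = 0, noise_sd = 0, seed = 1)
  expect_equal(detection_coverage(clean), 1.0)
  dog <- clean$records[clean$records$object == "dog", ]
  expect_equal(cbind(dog$cx, dog$cy), unname(path$dog))

  none <- corrupt_detections(path, miss_rate = 1, seed = 1)
  expect_equal(detection_coverage(none), 0.0)

  some <- corrupt_detections(path, miss_rate = 0.2, seed = 11)
  missing_frac <- mean(!some$records$detected)
  ci <- stats::qbinom(c(0.005, 0.995), 2000, 0.2) / 2000
  expect_gte(missing_frac, ci[1])
  expect_lte(missing_frac, ci[2])
  expect_error(corrupt_detections(path, noise_sd = -1), "non-negative")
})

test_that("ratings reproduce a fixed agreement breakdown exactly", {
  # 26 unanimous-neutral, 6 majority-neutral, 12 unanimous-towards,
  # 6 majority-towards
  styles <- c(rep("neutral", 32), rep("towards", 18))
  unanimous <- c(rep(TRUE, 26), rep(FALSE, 6), rep(TRUE, 12), rep(FALSE, 6))
  r <- generate_ratings(styles, seed = 4, unanimous = unanimous)
  expect_equal(sum(r$majority == "0"), 32)
  expect_equal(sum(r$majority == "+"), 18)
  votes <- collapse_and_vote(r)
  expect_identical(votes$majority, r$majority)
})

test_that("rating agreement follows the unanimity structure", {
  styles <- rep(c("neutral", "towards"), 25)
  all_unan <- generate_ratings(styles, unanimity_fraction = 1, seed = 2)
  expect_equal(percent_agreement(all_unan[, c("rater1", "rater2", "rater3")]),
               1.0)
  # 38 unanimous + 12 two-one splits: Po = (38 + 12/3) / 50 = 0.84
  unan <- c(rep(TRUE, 38), rep(FALSE, 12))
  mixed <- generate_ratings(styles, seed = 2, unanimous = unan)
  expect_equal(percent_agreement(mixed[, c("rater1", "rater2", "rater3")]),
               0.84)
  expect_true(all(table(mixed$trial_id) == 1))
  expect_true(all(!is.na(mixed$majority)))
})

test_that("C-BARQ scores live in [0,4] with the calibrated SDF medians", {
  n_half <- 1500
  styles <- c(rep("neutral", n_half), rep("towards", n_half))
  cov <- data.frame(mean_speed = rep(c(0.75, 2.1), each = n_half),
                    frac_near_tp = rep(c(0.05, 0.9), each = n_half))
  cb <- generate_cbarq(styles, cov, seed = 8)
  scores <- as.matrix(cb[, cbarq_categories()])
  expect_true(all(scores >= 0 & scores <= 4))
  expect_equal(median(cb$SDF[styles == "neutral"]), 0.00, tolerance = 0.02)
  expect_equal(median(cb$SDF[styles == "towards"]), 0.42, tolerance = 0.03)
})

test_that("noiseless excitability is an exact function of its covariates", {
  coup <- default_cbarq_coupling()
  coup$EXC$noise_sd <- 0
  styles <- rep(c("neutral", "towards"), 20)
  cov <- data.frame(mean_speed = runif(40, 0.5, 2.5),
                    frac_near_tp = runif(40, 0, 1))
  cb <- generate_cbarq(styles, cov, coupling = coup, seed = 1)
  fit <- lm(cb$EXC ~ cov$mean_speed + cov$frac_near_tp)
  expect_equal(suppressWarnings(summary(fit)$r.squared), 1.0,
               tolerance = 1e-9)
})

test_that("an identical cohort config yields byte-identical files", {
  cfg <- small_cohort_config(seed = 31, n_trials = 4, duration = 4)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohorts carry three ratings and a defined majority per trial", {
  co <- simulate_cohort(small_cohort_config(seed = 17, n_trials = 9,
                                            duration = 4))
  expect_equal(nrow(co$ratings), 9)
  expect_true(all(!is.na(co$ratings$majority)))
  sym <- c(towards = "+", neutral = "0", away = "-")
  expect_identical(unname(sym[co$truth$style]), co$ratings$majority)
})
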