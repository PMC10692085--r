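test_that("detection files round-trip through JSON", {
  path <- generate_trajectory("neutral", seed = 21, n_frames = 60)
  trial <- corrupt_detections(path, miss_rate = 0.1, noise_sd = 0.01,
                              seed = 3, trial_id = "rt_01")
  f <- tempfile(fileext = ".json")
  write_detections(trial, f)
  back <- read_detections(f)
  expect_identical(back$trial_id, trial$trial_id)
  expect_equal(back$fps, trial$fps)
  expect_equal(back$records$detected, trial$records$detected)
  det <- trial$records$detected
  for (col in c("cx", "cy", "x_min", "y_max", "conf"))
    expect_equal(back$records[[col]][det], trial$records[[col]][det],
                 tolerance = 1e-12)
  unlink(f)
})

test_that("frames or objects absent from the file become undetected", {
  f <- tempfile(fileext = ".json")
  writeLines('{
    "trial_id": "gap", "fps": 24,
    "calibration": {"px_per_m": 1, "origin": [0, 0]},
    "frames": [
      {"i": 0, "dog": {"bbox": [1, 1, 2, 2], "conf": 0.9},
               "person": {"bbox": [2, 2, 3, 3], "conf": 0.9}},
      {"i": 2, "person": {"bbox": [2, 2, 3, 3], "conf": 0.9}}
    ]}', f)
  tr <- read_detections(f)
  rec <- tr$records
  expect_equal(sort(unique(rec$frame)), 0:2)  # frame 1 materialized
  dog <- rec[rec$object == "dog", ]
  expect_identical(dog$detected, c(TRUE, FALSE, FALSE))
  expect_equal(dog$cx[1], 1.5)  # bbox midpoint
  unlink(f)
})

test_that("an inverted bounding box is rejected with frame and field", {
  f <- tempfile(fileext = ".json")
  writeLines('{
    "trial_id": "bad", "fps": 24,
    "frames": [{"i": 4, "dog": {"bbox": [5, 5, 3, 9], "conf": 0.9}}]}', f)
  expect_error(read_detections(f), "frame 4.*x_min/x_max")
  unlink(f)
})

test_that("joint coverage counts frames where both objects are detected", {
  path <- generate_trajectory("neutral", seed = 2, n_frames = 50)
  tr <- corrupt_detections(path, miss_rate = 0, seed = 1)
  expect_equal(detection_coverage(tr), 1.0)
  # knock out the dog in 10 frames
  rec <- tr$records
  rec$detected[rec$object == "dog" & rec$frame < 10] <- FALSE
  tr2 <- trial_detections("partial", 24, rec)
  expect_equal(detection_coverage(tr2), 0.8)
})

test_that("the quality gate is inclusive at the threshold and monotone", {
  make_cov <- function(id, n_both) {
    path <- generate_trajectory("neutral", seed = 5, n_frames = 100)
    tr <- corrupt_detections(path, miss_rate = 0, seed = 1, trial_id = id)
    rec <- tr$records
    drop <- rec$object == "dog" & rec$frame >= n_both
    rec$detected[drop] <- TRUE  # keep valid boxes, flip flag below
    rec$detected[rec$object == "dog" & rec$frame >= n_both] <- FALSE
    trial_detections(id, 24, rec)
  }
  trials <- list(make_cov("a", 79), make_cov("b", 80), make_cov("c", 81))
  qf <- quality_filter(trials, threshold = 0.8)
  expect_equal(qf$report$coverage, c(0.79, 0.80, 0.81))
  expect_identical(vapply(qf$retained, function(t) t$trial_id, ""),
                   c("b", "c"))
  # threshold 1.0 excludes anything with a gap
  expect_length(quality_filter(trials, threshold = 1.0)$retained, 0)
  # monotone: retained set only shrinks as the threshold rises
  for (t2 in c(0.5, 0.795, 0.81, 0.9)) {
    r1 <- quality_filter(trials, 0.4)$report$retained
    r2 <- quality_filter(trials, t2)$report$retained
    expect_true(all(r1 >= r2))
  }
})

test_that("gap filling interpolates interior gaps and holds the edges", {
  dog <- matrix(c(0:10, 0:10), ncol = 2) / 5
  tr <- perfect_trial(dog, trial_id = "interp")
  rec <- tr$records
  rec$detected[rec$object == "dog" & rec$frame %in% c(0, 5, 10)] <- FALSE
  gappy <- trial_detections("interp", 24, rec)
  filled <- fill_gaps(gappy, smooth_window = 1)
  d <- filled$records[filled$records$object == "dog", ]
  expect_equal(detection_coverage(filled), 1.0)
  expect_equal(d$cx[6], (d$cx[5] + d$cx[7]) / 2)  # interior midpoint
  expect_equal(d$cx[1], d$cx[2])                  # leading edge held
  expect_equal(d$cx[11], d$cx[10])                # trailing edge held
  expect_true(all(d$imputed == (d$frame %in% c(0, 5, 10))))
  # observed points untouched when smoothing is off
  expect_equal(d$cx[3], dog[3, 1])
})

test_that("gap filling is idempotent and fixes constants", {
  path <- generate_trajectory("towards", seed = 9, n_frames = 80)
  tr <- corrupt_detections(path, miss_rate = 0.2, seed = 2)
  f1 <- fill_gaps(tr)
  f2 <- fill_gaps(f1)
  expect_equal(f1$records, f2$records)
  const <- perfect_trial(matrix(1.7, 50, 2))
  rec0 <- const$records
  rec0$detected[rec0$object == "dog" & rec0$frame == 25] <- FALSE
  sm <- fill_gaps(trial_detections("const", 24, rec0), smooth_window = 5)
  expect_equal(sm$records$cx[sm$records$object == "dog"], rep(1.7, 50))
  # an object never detected cannot be reconstructed
  rec <- tr$records
  rec$detected[rec$object == "person"] <- FALSE
  expect_error(fill_gaps(trial_detections("x", 24, rec)),
               "'person' never detected")
})

test_that("resampling preserves linear signals and durations", {
  # ramp x(t) = t at 30 fps -> exact at 24 fps timestamps
  n30 <- 90
  t30 <- (seq_len(n30) - 1) / 30
  dog <- cbind(t30, t30) / 2
  tr <- perfect_trial(dog, fps = 30)
  rs <- resample_trial(fill_gaps(tr, smooth_window = 1), 24)
  d <- rs$records[rs$records$object == "dog", ]
  expect_equal(rs$fps, 24)
  expect_equal(d$cx, ((seq_len(nrow(d)) - 1) / 24) / 2, tolerance = 1e-12)
  # 60 s at 30 fps -> 1440 frames at 24 fps
  tr60 <- perfect_trial(matrix(1, 1800, 2), fps = 30)
  expect_equal(sum(resample_trial(tr60, 24)$records$object == "dog"), 1440)
  # identity at the native rate
  tr24 <- perfect_trial(dog, fps = 24)
  expect_identical(resample_trial(tr24, 24), tr24)
  expect_error(resample_trial(tr24, 0), "positive")
})

test_that("round-trip resampling reproduces a linear signal exactly", {
  t24 <- (0:239) / 24
  tr <- perfect_trial(cbind(0.5 + 0.05 * t24, 2 - 0.02 * t24), fps = 24)
  back <- resample_trial(resample_trial(tr, 30), 24)
  d0 <- tr$records[tr$records$object == "dog", ]
  d1 <- back$records[back$records$object == "dog", ]
  m <- nrow(d1)
  expect_equal(d1$cx, d0$cx[seq_len(m)], tolerance = 1e-12)
})

test_that("dataset assembly truncates to the shortest trial", {
  mk <- function(sec, id) perfect_trial(matrix(runif(sec * 24 * 2), ncol = 2),
                                        trial_id = id)
  trials <- list(mk(58, "a"), mk(60, "b"), mk(62, "c"))
  ds <- build_dataset(trials)
  expect_equal(ds$m_time, 58 * 24)
  expect_equal(dim(ds$matrix), c(3, 4 * 58 * 24))
  expect_identical(ds$trial_ids, c("a", "b", "c"))
  # flattening order: frame-major blocks of (dog_x, dog_y, person_x, person_y)
  expect_equal(ds$matrix[2, 1:4], unname(ds$array[2, 1, ]))
  expect_equal(ds$matrix[1, 5:8], unname(ds$array[1, 2, ]))
  expect_error(build_dataset(trials[1]), "at least 2")
  expect_error(build_dataset(list(mk(58, "a"), mk(0.5, "tiny"))),
               "shorter than 1 s")
})
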