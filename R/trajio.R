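#' Per-trial detection container
#'
#' Holds the per-frame dog/person detections of one trial, as produced by
#' an overhead object detector, together with the frame rate and a
#' pixel-to-meter calibration. Frames are 0-based; the bounding-box center
#' is used as the animal's center-of-mass proxy.
#'
#' @param trial_id Trial identifier.
#' @param fps Frames per second.
#' @param records Data frame with columns `frame`, `object` ("dog" or
#'   "person"), `detected`, `cx`, `cy`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `conf`. Missing detections carry `detected = FALSE` and NA
#'   coordinates. An `imputed` logical column is added by [fill_gaps()].
#' @param calibration List with `px_per_m` (scale) and `origin` (2-vector);
#'   the identity calibration means coordinates are already in meters.
#' @return An object of class `trial_detections`.
#' @export
trial_detections <- function(trial_id, fps, records,
                             calibration = list(px_per_m = 1,
                                                origin = c(0, 0))) {
  stopifnot(is.data.frame(records), fps > 0)
  needed <- c("frame", "object", "detected", "cx", "cy",
              "x_min", "y_min", "x_max", "y_max", "conf")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  for (obj in c("dog", "person")) {
    sub <- records[records$object == obj, ]
    if (anyDuplicated(sub$frame))
      stop("duplicate frames for object '", obj, "'")
  }
  bad <- which(records$detected &
                 (records$x_min > records$x_max |
                    records$y_min > records$y_max))
  if (length(bad)) {
    r <- records[bad[1], ]
    fld <- if (r$x_min > r$x_max) "x_min/x_max" else "y_min/y_max"
    stop("invalid bounding box at frame ", r$frame, " (", r$object,
         "): ", fld, " inverted")
  }
  records <- records[order(records$object, records$frame), ]
  rownames(records) <- NULL
  if (is.null(records$imputed)) records$imputed <- FALSE
  structure(list(trial_id = trial_id, fps = fps, records = records,
                 calibration = calibration),
            class = "trial_detections")
}

#' @export
print.trial_detections <- function(x, ...) {
  nf <- length(unique(x$records$frame))
  cat("<trial_detections> ", x$trial_id, ": ", nf, " frames @ ", x$fps,
      " fps, joint coverage ",
      sprintf("%.3f", detection_coverage(x)), "\n", sep = "")
  invisible(x)
}

#' Write trial detections as JSON
#'
#' Schema: `{trial_id, fps, calibration:{px_per_m, origin}, frames:[{i,
#' dog:{bbox:[x_min,y_min,x_max,y_max], conf}|null, person:{...}|null}]}`.
#'
#' @param trial A `trial_detections` object.
#' @param path Output file.
#' @export
write_detections <- function(trial, path) {
  rec <- trial$records
  frames <- sort(unique(rec$frame))
  obj_entry <- function(r) {
    if (nrow(r) == 0 || !r$detected[1]) return(NULL)
    list(bbox = c(r$x_min[1], r$y_min[1], r$x_max[1], r$y_max[1]),
         conf = r$conf[1])
  }
  frame_list <- lapply(frames, function(f) {
    d <- obj_entry(rec[rec$frame == f & rec$object == "dog", ])
    p <- obj_entry(rec[rec$frame == f & rec$object == "person", ])
    out <- list(i = f)
    out$dog <- d
    out$person <- p
    out
  })
  jsonlite::write_json(
    list(trial_id = trial$trial_id, fps = trial$fps,
         calibration = list(px_per_m = trial$calibration$px_per_m,
                            origin = trial$calibration$origin),
         frames = frame_list),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read trial detections from JSON
#'
#' Inverse of [write_detections()]. Every frame index in `[0, last]` is
#' represented in the result; frames absent from the file (or objects
#' absent from a frame) become `detected = FALSE` records. Malformed
#' bounding boxes are rejected with the offending frame and field named.
#'
#' @param path JSON file.
#' @return A `trial_detections` object.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path)
  stopifnot(!is.null(j$trial_id), !is.null(j$fps), !is.null(j$frames))
  present <- vapply(j$frames, function(f) as.integer(f$i), integer(1))
  last <- if (length(present)) max(present) else -1L
  one <- function(object) {
    n <- last + 1L
    out <- data.frame(frame = seq_len(n) - 1L, object = object,
                      detected = FALSE, cx = NA_real_, cy = NA_real_,
                      x_min = NA_real_, y_min = NA_real_,
                      x_max = NA_real_, y_max = NA_real_, conf = NA_real_)
    for (f in j$frames) {
      e <- f[[object]]
      if (is.null(e)) next
      i <- as.integer(f$i) + 1L
      bb <- as.numeric(unlist(e$bbox))
      if (length(bb) != 4)
        stop("frame ", f$i, " (", object, "): bbox must have 4 numbers")
      out$detected[i] <- TRUE
      out[i, c("x_min", "y_min", "x_max", "y_max")] <- as.list(bb)
      out$cx[i] <- (bb[1] + bb[3]) / 2
      out$cy[i] <- (bb[2] + bb[4]) / 2
      out$conf[i] <- if (is.null(e$conf)) NA_real_ else as.numeric(e$conf)
    }
    out
  }
  calib <- list(px_per_m = 1, origin = c(0, 0))
  if (!is.null(j$calibration)) {
    calib$px_per_m <- as.numeric(j$calibration$px_per_m)
    calib$origin <- as.numeric(unlist(j$calibration$origin))
  }
  trial_detections(trial_id = j$trial_id, fps = as.numeric(j$fps),
                   records = rbind(one("dog"), one("person")),
                   calibration = calib)
}

#' Joint detection coverage of a trial
#'
#' Fraction of frames in which BOTH the dog and the person are detected —
#' the quantity the 80% quality gate operates on.
#'
#' @param trial A `trial_detections` object.
#' @return Fraction in [0, 1].
#' @export
detection_coverage <- function(trial) {
  rec <- trial$records
  frames <- unique(rec$frame)
  if (length(frames) == 0) stop("trial has no frames")
  dog <- rec$detected[rec$object == "dog"][order(rec$frame[rec$object == "dog"])]
  per <- rec$detected[rec$object == "person"][order(rec$frame[rec$object == "person"])]
  mean(dog & per)
}

#' Quality gate on detection coverage
#'
#' Retains trials whose joint detection coverage is at least `threshold`
#' (inclusive, reading "at least 80%" as >= 0.80) and reports the rest.
#'
#' @param trials List of `trial_detections`.
#' @param threshold Minimum joint coverage, in (0, 1].
#' @return List with `retained` (sub-list of trials) and `report` (data
#'   frame: trial_id, coverage, retained).
#' @export
quality_filter <- function(trials, threshold = 0.80) {
  stopifnot(threshold > 0, threshold <= 1)
  cov <- vapply(trials, detection_coverage, numeric(1))
  ids <- vapply(trials, function(t) t$trial_id, character(1))
  keep <- cov >= threshold
  list(retained = trials[keep],
       report = data.frame(trial_id = ids, coverage = cov,
                           retained = keep, row.names = NULL))
}

#' Fill detection gaps and smooth
#'
#' Interior gaps in each object's center track are filled by linear
#' interpolation between the flanking detections; leading/trailing gaps
#' hold the nearest detected value (slope extrapolation can exit the
#' arena, clamping cannot). A centered moving average of width
#' `smooth_window` (edges shrunk) is then applied to the completed track.
#' Post-fill joint coverage is 1 by construction, clearing the "above
#' 95%" post-processing requirement.
#'
#' @param trial A `trial_detections` object.
#' @param smooth_window Odd moving-average width in frames; 1 disables
#'   smoothing.
#' @return A complete `trial_detections` (all `detected = TRUE`, imputed
#'   frames flagged in the `imputed` column).
#' @export
fill_gaps <- function(trial, smooth_window = 5) {
  stopifnot(smooth_window >= 1)
  rec <- trial$records
  # an already-complete trial is returned untouched (makes filling
  # idempotent: smoothing belongs to the imputation pass, applied once)
  if (all(rec$detected)) return(trial)
  half <- c(dog = 0.25, person = 0.30)
  for (obj in c("dog", "person")) {
    idx <- which(rec$object == obj)
    sub <- rec[idx, ]
    sub <- sub[order(sub$frame), ]
    if (!any(sub$detected))
      stop("object '", obj, "' never detected in trial ", trial$trial_id)
    for (col in c("cx", "cy")) {
      v <- sub[[col]]
      v[!sub$detected] <- NA_real_
      v <- zoo::na.approx(v, x = sub$frame, na.rm = FALSE, rule = 2)
      if (smooth_window > 1)
        v <- zoo::rollapply(v, smooth_window, mean, partial = TRUE,
                            align = "center")
      sub[[col]] <- v
    }
    h <- half[[obj]] * trial$calibration$px_per_m
    sub$x_min <- sub$cx - h; sub$x_max <- sub$cx + h
    sub$y_min <- sub$cy - h; sub$y_max <- sub$cy + h
    sub$imputed <- sub$imputed | !sub$detected
    sub$detected <- TRUE
    rec[idx, ] <- sub
  }
  trial_detections(trial$trial_id, trial$fps, rec, trial$calibration)
}

#' Resample a gap-free trial to a target frame rate
#'
#' Center coordinates are linearly interpolated at the target-rate
#' timestamps `0, 1/fps, 2/fps, ...`; the number of output frames is
#' `floor(duration * target_fps)` so the duration is preserved to within
#' one frame period. A trial already at the target rate is returned
#' unchanged.
#'
#' @param trial A complete (gap-free) `trial_detections`.
#' @param target_fps Target frame rate; default 24 (the standardized rate
#'   used across all trials).
#' @return A `trial_detections` at `target_fps`.
#' @export
resample_trial <- function(trial, target_fps = 24) {
  if (target_fps <= 0) stop("target_fps must be positive")
  if (trial$fps == target_fps) return(trial)
  rec <- trial$records
  if (!all(rec$detected)) stop("trial must be gap-free; run fill_gaps first")
  out <- NULL
  half <- c(dog = 0.25, person = 0.30)
  for (obj in c("dog", "person")) {
    sub <- rec[rec$object == obj, ]
    sub <- sub[order(sub$frame), ]
    t_old <- sub$frame / trial$fps
    # last target timestamp never exceeds the native range (no extrapolation)
    n_new <- floor((nrow(sub) - 1L) / trial$fps * target_fps) + 1L
    t_new <- (seq_len(n_new) - 1L) / target_fps
    cx <- stats::approx(t_old, sub$cx, xout = t_new, rule = 2)$y
    cy <- stats::approx(t_old, sub$cy, xout = t_new, rule = 2)$y
    imp <- stats::approx(t_old, as.numeric(sub$imputed), xout = t_new,
                         rule = 2)$y > 0
    h <- half[[obj]] * trial$calibration$px_per_m
    out <- rbind(out, data.frame(
      frame = seq_len(n_new) - 1L, object = obj, detected = TRUE,
      cx = cx, cy = cy, x_min = cx - h, y_min = cy - h,
      x_max = cx + h, y_max = cy + h, conf = NA_real_, imputed = imp))
  }
  trial_detections(trial$trial_id, target_fps, out, trial$calibration)
}

#' Assemble the fixed-length trajectory dataset
#'
#' Converts each complete trial to meters via its calibration, truncates
#' every trial (from its start) to the shortest trial's frame count, and
#' stacks the cohort into an `n x (4 m)` matrix. Row i is trial i's
#' time-major flattening: for each frame in order, the four channels
#' (dog_x, dog_y, person_x, person_y).
#'
#' @param trials List of gap-free `trial_detections` at a common fps.
#' @return An object of class `trajectory_dataset`: list with `trial_ids`,
#'   `fps`, `m_time`, `array` (n x m_time x 4) and `matrix` (n x 4 m_time).
#' @export
build_dataset <- function(trials) {
  if (length(trials) < 2) stop("need at least 2 trials to build a dataset")
  fps <- unique(vapply(trials, function(t) t$fps, numeric(1)))
  if (length(fps) != 1) stop("all trials must share one fps; resample first")
  n_frames <- vapply(trials, function(t) sum(t$records$object == "dog"),
                     integer(1))
  if (any(n_frames < fps)) stop("trial shorter than 1 s: ",
                                paste(vapply(trials[n_frames < fps],
                                             function(t) t$trial_id,
                                             character(1)), collapse = ", "))
  m_time <- min(n_frames)
  n <- length(trials)
  A <- array(NA_real_, c(n, m_time, 4),
             dimnames = list(NULL, NULL,
                             c("dog_x", "dog_y", "person_x", "person_y")))
  ids <- character(n)
  for (i in seq_len(n)) {
    tr <- trials[[i]]
    rec <- tr$records
    if (!all(rec$detected)) stop("trial ", tr$trial_id, " has gaps")
    calib <- tr$calibration
    to_m <- function(v, ax) (v - calib$origin[ax]) / calib$px_per_m
    for (k in seq_len(2)) {
      obj <- c("dog", "person")[k]
      sub <- rec[rec$object == obj, ]
      sub <- sub[order(sub$frame), ][seq_len(m_time), ]
      A[i, , 2 * k - 1] <- to_m(sub$cx, 1)
      A[i, , 2 * k]     <- to_m(sub$cy, 2)
    }
    ids[i] <- tr$trial_id
  }
  D <- matrix(aperm(A, c(3, 2, 1)), nrow = n, byrow = TRUE)
  rownames(D) <- ids
  structure(list(trial_ids = ids, fps = fps, m_time = m_time,
                 array = A, matrix = D),
            class = "trajectory_dataset")
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat("<trajectory_dataset> ", length(x$trial_ids), " trials x ",
      x$m_time, " frames @ ", x$fps, " fps (matrix ",
      nrow(x$matrix), " x ", ncol(x$matrix), ")\n", sep = "")
  invisible(x)
}

#' Preprocess a cohort of raw detections into the analysis dataset
#'
#' The standard post-detection chain: quality gate at `min_coverage`
#' joint coverage, gap filling + smoothing, frame-rate standardization,
#' and shortest-duration truncation into a `trajectory_dataset`.
#'
#' @param trials List of `trial_detections`.
#' @param min_coverage Quality-gate threshold (default 0.80).
#' @param smooth_window Moving-average width (frames).
#' @param target_fps Standardized frame rate (default 24).
#' @return List with `dataset`, `report` (the quality-gate report) and
#'   `post_fill_coverage` (named per-trial joint coverage after filling).
#' @export
preprocess_cohort <- function(trials, min_coverage = 0.80,
                              smooth_window = 5, target_fps = 24) {
  qf <- quality_filter(trials, threshold = min_coverage)
  filled <- lapply(qf$retained, fill_gaps, smooth_window = smooth_window)
  post <- vapply(filled, detection_coverage, numeric(1))
  names(post) <- vapply(filled, function(t) t$trial_id, character(1))
  std <- lapply(filled, resample_trial, target_fps = target_fps)
  list(dataset = build_dataset(std), report = qf$report,
       post_fill_coverage = post)
}
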