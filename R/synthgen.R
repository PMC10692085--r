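#' Generate one synthetic dog trajectory
#'
#' Simulates the dog's center-of-mass path during the test phase as a
#' discrete-time Ornstein-Uhlenbeck-like walk,
#' \deqn{x_{t+1} = x_t + a (m(x_t) - x_t) \Delta t + w(x_t) \Delta t +
#'   \sigma \sqrt{\Delta t}\, \epsilon_t,}
#' where the set point \eqn{m(x)} lies on the ray from the test person (TP)
#' through the dog at the style's preferred TP distance, \eqn{w} is a soft
#' wall-avoidance force active within a small margin of the fence, and the
#' walls reflect. The stranger is seated and static, so the person path is
#' constant at `arena$tp_position`. The dog enters at the gate (middle of
#' the front fence).
#'
#' @param style One of [coping_styles()].
#' @param arena An [arena_spec()].
#' @param params Motion parameters for this style (see
#'   [default_motion_params()]).
#' @param seed Integer seed; if `NULL`, the current RNG stream is used.
#' @param n_frames Number of frames; default `round(duration * fps)` with
#'   no jitter (jitter is applied at cohort level).
#' @return List with `dog` and `person` (`n_frames` x 2 matrices, meters),
#'   `fps`, and `style`.
#' @export
generate_trajectory <- function(style, arena = arena_spec(),
                                params = default_motion_params()[[style]],
                                seed = NULL, n_frames = NULL) {
  assert_style(style)
  stopifnot(inherits(arena, "arena_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_frames)) n_frames <- round(arena$duration * arena$fps)
  stopifnot(n_frames >= 1)
  dt <- 1 / arena$fps
  side <- arena$side_length
  tp <- arena$tp_position
  dog <- matrix(NA_real_, n_frames, 2)
  # entry at the gate: middle of the front fence, facing the TP
  x <- c(side / 2, 0.30)
  sqdt <- sqrt(dt)
  for (t in seq_len(n_frames)) {
    dog[t, ] <- x
    v <- x - tp
    d <- sqrt(sum(v * v))
    u <- if (d > 1e-9) v / d else {
      th <- stats::runif(1, 0, 2 * pi)
      c(cos(th), sin(th))
    }
    setpt <- tp + u * params$pref_dist
    drift <- params$attraction * (setpt - x) * dt
    m <- params$wall_margin
    wall <- params$wall * dt *
      (pmax(0, m - x) / m - pmax(0, m - (side - x)) / m)
    x <- x + drift + wall + params$sigma * sqdt * stats::rnorm(2)
    # reflecting boundaries
    x <- abs(x)
    over <- x > side
    x[over] <- 2 * side - x[over]
    x <- pmin(pmax(x, 0), side)
  }
  person <- matrix(rep(tp, each = n_frames), n_frames, 2)
  list(dog = dog, person = person, fps = arena$fps, style = style)
}

#' Corrupt perfect paths into imperfect per-frame detections
#'
#' Emulates an object detector's output on the overhead video: each frame
#' independently loses the dog and/or the person detection with probability
#' `miss_rate`, and detected centers are perturbed by isotropic Gaussian
#' noise of standard deviation `noise_sd`. Bounding boxes are centered on
#' the (noisy) centers with fixed object half-sizes.
#'
#' @param paths Output of [generate_trajectory()].
#' @param miss_rate Per-frame, per-object missed-detection probability.
#' @param noise_sd Center localization noise, meters.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param trial_id Trial identifier stored in the output.
#' @return A `trial_detections` object (see [trial_detections()]).
#' @export
corrupt_detections <- function(paths, miss_rate = 0.05, noise_sd = 0.02,
                               seed = NULL, trial_id = "trial") {
  stopifnot(miss_rate >= 0, miss_rate <= 1)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(paths$dog)
  half <- c(dog = 0.25, person = 0.30)  # object half-extents, m
  one_object <- function(xy, object) {
    det <- stats::runif(n) >= miss_rate
    cx <- xy[, 1] + stats::rnorm(n, 0, noise_sd)
    cy <- xy[, 2] + stats::rnorm(n, 0, noise_sd)
    cx[!det] <- NA_real_
    cy[!det] <- NA_real_
    h <- half[[object]]
    data.frame(
      frame = seq_len(n) - 1L, object = object, detected = det,
      cx = cx, cy = cy,
      x_min = cx - h, y_min = cy - h, x_max = cx + h, y_max = cy + h,
      conf = ifelse(det, stats::runif(n, 0.8, 1.0), NA_real_))
  }
  records <- rbind(one_object(paths$dog, "dog"),
                   one_object(paths$person, "person"))
  trial_detections(trial_id = trial_id, fps = paths$fps, records = records)
}

#' Generate three-rater coping-style scores
#'
#' Three expert raters score each trial on the collapsed three-class scale
#' ('-', '0', '+'). A trial is unanimous with probability
#' `unanimity_fraction`; otherwise the score is a 2:1 split with the
#' dissenting rater (chosen at random) drawn to a category adjacent to the
#' true one on the ordinal '-' < '0' < '+' scale. The majority vote
#' therefore always equals the true style.
#'
#' @param true_styles Character vector of [coping_styles()], one per trial.
#' @param unanimity_fraction Probability a trial is rated unanimously.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param unanimous Optional logical vector overriding the random
#'   unanimity draw trial-by-trial (used to reproduce a fixed agreement
#'   breakdown exactly).
#' @param trial_ids Optional trial identifiers.
#' @return Data frame with `trial_id`, `rater1..rater3` (symbols),
#'   `majority`, `unanimous`.
#' @export
generate_ratings <- function(true_styles, unanimity_fraction = 0.76,
                             seed = NULL, unanimous = NULL,
                             trial_ids = NULL) {
  stopifnot(unanimity_fraction >= 0, unanimity_fraction <= 1)
  vapply(true_styles, assert_style, character(1))
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_styles)
  if (is.null(trial_ids)) trial_ids <- sprintf("trial_%03d", seq_len(n))
  sym <- c(towards = "+", neutral = "0", away = "-")[true_styles]
  if (is.null(unanimous)) unanimous <- stats::runif(n) < unanimity_fraction
  stopifnot(length(unanimous) == n)
  adjacent <- function(s) switch(s, "+" = "0", "-" = "0",
                                 "0" = sample(c("-", "+"), 1))
  r <- matrix(rep(sym, 3), n, 3)
  for (i in which(!unanimous)) {
    r[i, sample.int(3, 1)] <- adjacent(sym[i])
  }
  data.frame(trial_id = trial_ids, rater1 = r[, 1], rater2 = r[, 2],
             rater3 = r[, 3], majority = unname(sym),
             unanimous = unanimous)
}

#' Default C-BARQ coupling coefficients
#'
#' Linear coupling of each of the 8 C-BARQ category scores to the trial's
#' coping style and trajectory activity covariates. Each score is
#' `clip(intercept + b_towards * I(towards) + b_away * I(away) +
#' b_speed * mean_speed + b_near * frac_near_tp + noise, 0, 4)`.
#' Stranger-directed fear (SDF) is driven by style (calibrated so that
#' neutral trials have median 0.00 and towards trials median 0.42);
#' excitability (EXC) is driven by the activity covariates (mean speed in
#' m/s and fraction of time within 1 m of the stranger); the remaining
#' categories are only weakly coupled. `noise_sd` is on the 0-4 score
#' scale.
#'
#' @return Named list of per-category coefficient lists.
#' @export
default_cbarq_coupling <- function() {
  weak <- function(intercept, noise_sd = 0.3)
    list(intercept = intercept, b_towards = 0.1, b_away = 0.1,
         b_speed = 0.05, b_near = 0.05, noise_sd = noise_sd)
  list(
    SDA = weak(0.5),
    ODA = weak(0.2),
    SDF = list(intercept = -0.30, b_towards = 0.72, b_away = 1.20,
               b_speed = 0, b_near = 0, noise_sd = 0.30),
    NSF = weak(0.9),
    SRB = weak(0.7),
    ASB = weak(1.5),
    EXC = list(intercept = -0.40, b_towards = 0, b_away = 0,
               b_speed = 0.80, b_near = 0.60, noise_sd = 0.10),
    PS  = weak(0.9)
  )
}

#' C-BARQ category order used throughout
#' @export
cbarq_categories <- function()
  c("SDA", "ODA", "SDF", "NSF", "SRB", "ASB", "EXC", "PS")

#' Generate owner-reported C-BARQ category profiles
#'
#' Each of the 8 category scores is a clipped-to-[0,4] linear function of
#' the trial's coping style indicator and activity covariates plus
#' Gaussian noise (see [default_cbarq_coupling()]).
#'
#' @param true_styles Character vector of coping styles, one per trial.
#' @param covariates Data frame with columns `mean_speed` (m/s) and
#'   `frac_near_tp` (fraction of frames within 1 m of the stranger).
#' @param coupling Per-category coefficients; default
#'   [default_cbarq_coupling()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param trial_ids Optional trial identifiers.
#' @return Data frame with `trial_id` and the 8 category columns.
#' @export
generate_cbarq <- function(true_styles, covariates,
                           coupling = default_cbarq_coupling(),
                           seed = NULL, trial_ids = NULL) {
  vapply(true_styles, assert_style, character(1))
  stopifnot(all(c("mean_speed", "frac_near_tp") %in% names(covariates)),
            nrow(covariates) == length(true_styles))
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_styles)
  if (is.null(trial_ids)) trial_ids <- sprintf("trial_%03d", seq_len(n))
  out <- data.frame(trial_id = trial_ids)
  for (cat in cbarq_categories()) {
    co <- coupling[[cat]]
    score <- co$intercept +
      co$b_towards * (true_styles == "towards") +
      co$b_away * (true_styles == "away") +
      co$b_speed * covariates$mean_speed +
      co$b_near * covariates$frac_near_tp +
      stats::rnorm(n, 0, co$noise_sd)
    out[[cat]] <- pmin(pmax(score, 0), 4)
  }
  out
}

#' Cohort configuration for the synthetic Stranger Test generator
#'
#' Bundles everything [simulate_cohort()] needs. Defaults emulate the
#' reference cohort: 46 trials, 28 neutral ('0') and 18 towards
#' ('+'), ~40 s trials at 24 fps in a 4.7 m arena, a 5% per-frame
#' missed-detection rate with 2 cm localization noise, and 76% unanimously
#' rated trials. `n_low_quality` trials (neutral-scored, mirroring the
#' three real exclusions) can be generated with a much higher miss rate so
#' they fall below the 80% coverage gate.
#'
#' @param n_trials Number of trials.
#' @param style_proportions Named numeric simplex over the three styles.
#' @param arena An [arena_spec()].
#' @param motion Per-style motion parameters.
#' @param miss_rate,noise_sd Detection corruption parameters.
#' @param unanimity_fraction Fraction of unanimously rated trials.
#' @param cbarq_coupling Per-category C-BARQ coefficients.
#' @param n_low_quality Number of additional low-coverage trials.
#' @param low_quality_miss_rate Miss rate used for those trials.
#' @param seed Integer seed driving the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_trials = 46,
                          style_proportions = c(towards = 18 / 46,
                                                neutral = 28 / 46,
                                                away = 0),
                          arena = arena_spec(),
                          motion = default_motion_params(),
                          miss_rate = 0.05,
                          noise_sd = 0.02,
                          unanimity_fraction = 0.76,
                          cbarq_coupling = default_cbarq_coupling(),
                          n_low_quality = 0,
                          low_quality_miss_rate = 0.35,
                          seed = 1L) {
  stopifnot(n_trials >= 1,
            abs(sum(style_proportions) - 1) < 1e-8,
            all(style_proportions >= 0),
            all(sort(names(style_proportions)) == sort(coping_styles())),
            miss_rate >= 0, miss_rate <= 1, noise_sd >= 0,
            unanimity_fraction >= 0, unanimity_fraction <= 1,
            n_low_quality >= 0, low_quality_miss_rate >= 0,
            low_quality_miss_rate <= 1)
  structure(
    list(n_trials = n_trials, style_proportions = style_proportions,
         arena = arena, motion = motion, miss_rate = miss_rate,
         noise_sd = noise_sd, unanimity_fraction = unanimity_fraction,
         cbarq_coupling = cbarq_coupling, n_low_quality = n_low_quality,
         low_quality_miss_rate = low_quality_miss_rate,
         seed = as.integer(seed)),
    class = "cohort_config")
}

# largest-remainder apportionment of n trials to styles
style_counts <- function(n, proportions) {
  raw <- proportions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  cnt
}

#' Simulate a complete synthetic arena cohort
#'
#' Generates, for each trial: a true dog/person path, corrupted per-frame
#' detections, and per-trial activity covariates; plus cohort-level rater
#' scores and C-BARQ profiles coupled to the hidden styles. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with `trials` (list of `trial_detections`), `truth`
#'   (data frame: trial_id, style, duration, mean_speed, frac_near_tp,
#'   low_quality), `ratings`, `cbarq`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  arena <- config$arena
  counts <- style_counts(config$n_trials, config$style_proportions)
  styles <- rep(names(counts), counts)
  low_quality <- rep(FALSE, length(styles))
  if (config$n_low_quality > 0) {
    # extra low-coverage trials; neutral-scored by convention
    styles <- c(styles, rep("neutral", config$n_low_quality))
    low_quality <- c(low_quality, rep(TRUE, config$n_low_quality))
  }
  n <- length(styles)
  ord <- sample.int(n)  # shuffle so styles are not blocked by trial id
  styles <- styles[ord]
  low_quality <- low_quality[ord]
  ids <- sprintf("trial_%03d", seq_len(n))

  trials <- vector("list", n)
  names(trials) <- ids
  truth <- data.frame(trial_id = ids, style = styles,
                      duration = NA_real_, mean_speed = NA_real_,
                      frac_near_tp = NA_real_, low_quality = low_quality)
  for (i in seq_len(n)) {
    dur <- arena$duration +
      stats::runif(1, -arena$duration_jitter, arena$duration_jitter)
    nf <- round(dur * arena$fps)
    paths <- generate_trajectory(styles[i], arena,
                                 config$motion[[styles[i]]],
                                 n_frames = nf)
    step <- sqrt(rowSums(diff(paths$dog)^2))
    dtp <- sqrt(rowSums((paths$dog -
                           matrix(arena$tp_position, nf, 2, byrow = TRUE))^2))
    truth$duration[i] <- nf / arena$fps
    truth$mean_speed[i] <- mean(step) * arena$fps
    truth$frac_near_tp[i] <- mean(dtp < 1.0)
    mr <- if (low_quality[i]) config$low_quality_miss_rate else config$miss_rate
    trials[[i]] <- corrupt_detections(paths, miss_rate = mr,
                                      noise_sd = config$noise_sd,
                                      trial_id = ids[i])
  }
  ratings <- generate_ratings(styles,
                              unanimity_fraction = config$unanimity_fraction,
                              trial_ids = ids)
  cbarq <- generate_cbarq(styles,
                          truth[, c("mean_speed", "frac_near_tp")],
                          coupling = config$cbarq_coupling,
                          trial_ids = ids)
  list(trials = trials, truth = truth, ratings = ratings, cbarq = cbarq,
       config = config)
}

#' Write a simulated cohort to disk
#'
#' One detection JSON per trial plus `ratings.csv`, `cbarq.csv`,
#' `truth.csv` (the hidden styles) and `manifest.json` recording the seed.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in cohort$trials)
    write_detections(tr, file.path(dir, paste0(tr$trial_id, ".json")))
  utils::write.csv(cohort$ratings, file.path(dir, "ratings.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$cbarq, file.path(dir, "cbarq.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_trials = length(cohort$trials), seed = cohort$config$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
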