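#' Arena specification for a Stranger Test trial
#'
#' Describes the physical test setup: a square fenced arena filmed in top
#' view, with the test person (TP, the stranger) seated at a fixed marked
#' position in the middle and the familiar person (FP) on a chair in a
#' corner. Defaults follow the standard setup: a 4.7 x 4.7 m arena, TP at
#' the arena center, 24 frames per second, and a ~40 s test phase.
#'
#' @param side_length Arena side, meters.
#' @param tp_position Test-person (stranger) chair position, meters; default
#'   the arena center.
#' @param fp_position Familiar-person chair position, meters (corner).
#' @param fps Video frame rate, frames per second.
#' @param duration Nominal trial duration, seconds.
#' @param duration_jitter Half-width of the uniform per-trial duration
#'   jitter, seconds, so cohorts contain unequal-length trials.
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(side_length = 4.7,
                       tp_position = c(side_length / 2, side_length / 2),
                       fp_position = c(0.35, 0.35),
                       fps = 24,
                       duration = 40,
                       duration_jitter = 2) {
  stopifnot(is.numeric(side_length), length(side_length) == 1L, side_length > 0)
  stopifnot(is.numeric(fps), length(fps) == 1L, fps > 0)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  stopifnot(duration_jitter >= 0, duration_jitter < duration)
  tp_position <- as.numeric(tp_position)
  fp_position <- as.numeric(fp_position)
  if (length(tp_position) != 2L || any(tp_position < 0) || any(tp_position > side_length))
    stop("tp_position must be a 2-D point inside the arena")
  if (length(fp_position) != 2L || any(fp_position < 0) || any(fp_position > side_length))
    stop("fp_position must be a 2-D point inside the arena")
  structure(
    list(side_length = side_length, tp_position = tp_position,
         fp_position = fp_position, fps = fps, duration = duration,
         duration_jitter = duration_jitter),
    class = "arena_spec")
}

#' Admissible coping styles
#'
#' The three coping styles a dog can display towards the stranger:
#' `"towards"` (reacting towards the stressor, '+'), `"neutral"` ('0') and
#' `"away"` (reacting away from the stressor, '-').
#'
#' @export
coping_styles <- function() c("towards", "neutral", "away")

assert_style <- function(style) {
  if (!(is.character(style) && length(style) == 1L && style %in% coping_styles()))
    stop("invalid coping style: ", paste(style, collapse = ", "),
         " (must be one of ", paste(coping_styles(), collapse = ", "), ")")
  invisible(style)
}

#' Default style-specific motion parameters
#'
#' Parameters of the stochastic motion model used by
#' [generate_trajectory()]: per coping style, the attraction rate `a`
#' (1/s) towards a style-specific set point, the exploration noise scale
#' `sigma` (m/sqrt(s)), the wall-avoidance strength (1/s, acting within
#' `wall_margin` meters of the fence), and the preferred distance from the
#' stranger (m). Dogs reacting towards the stranger hold a short preferred
#' distance and move fast; neutral dogs keep a moderate distance while
#' exploring; dogs reacting away keep near the fence, far from the TP.
#'
#' @return Named list of per-style parameter lists.
#' @export
default_motion_params <- function() {
  list(
    towards = list(attraction = 2.0, sigma = 0.35, wall = 2.0,
                   wall_margin = 0.25, pref_dist = 0.4),
    neutral = list(attraction = 0.25, sigma = 0.12, wall = 2.0,
                   wall_margin = 0.25, pref_dist = 1.5),
    away    = list(attraction = 1.2, sigma = 0.18, wall = 2.0,
                   wall_margin = 0.25, pref_dist = 3.1)
  )
}
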