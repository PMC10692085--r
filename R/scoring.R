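#' Collapse raw expert scores to the three-class scale
#'
#' The experts score on a five-point -2..+2 scale; the analysis groups the
#' negative (-2, -1) and positive (+1, +2) scores, giving the three
#' classes '-', '0', '+'. Already-collapsed symbols pass through.
#'
#' @param score Vector of raw scores in \{-2,...,+2\} or symbols
#'   '-', '0', '+'.
#' @return Character vector of symbols.
#' @export
collapse_score <- function(score) {
  if (is.character(score) || is.factor(score)) {
    score <- as.character(score)
    bad <- !score %in% c("-", "0", "+")
    if (any(bad)) stop("invalid collapsed score: ", score[bad][1])
    return(score)
  }
  if (any(!score %in% -2:2))
    stop("raw score outside {-2,...,+2}: ", score[!score %in% -2:2][1])
  c("-", "0", "+")[sign(score) + 2]
}

#' Collapse three raters' scores and take the majority vote
#'
#' Each trial's three raw scores are collapsed to '-'/'0'/'+' and the
#' final label is the class chosen by at least two raters (e.g. two '+'
#' and one '0' gives '+'). A three-way split has no majority: it is
#' flagged and the label left `NA`, never imputed.
#'
#' @param ratings Data frame with columns `rater1`, `rater2`, `rater3`
#'   (raw -2..+2 or collapsed symbols) and optionally `trial_id`.
#' @return The input with collapsed rater columns plus `majority`
#'   (character, `NA` on ties) and `tie` (logical).
#' @export
collapse_and_vote <- function(ratings) {
  stopifnot(all(c("rater1", "rater2", "rater3") %in% names(ratings)))
  out <- ratings
  for (col in c("rater1", "rater2", "rater3"))
    out[[col]] <- collapse_score(ratings[[col]])
  m <- as.matrix(out[, c("rater1", "rater2", "rater3")])
  vote <- apply(m, 1, function(r) {
    tab <- sort(table(r), decreasing = TRUE)
    if (tab[1] >= 2) names(tab)[1] else NA_character_
  })
  out$majority <- vote
  out$tie <- is.na(vote)
  out
}

#' Fleiss-style observed pairwise agreement
#'
#' Mean over subjects of the fraction of agreeing rater pairs (3 pairs for
#' 3 raters): a unanimous subject contributes 1, a 2:1 split 1/3, a
#' three-way split 0.
#'
#' @param ratings Matrix or data frame of collapsed categories, one row
#'   per subject, one column per rater; no missing values allowed.
#' @return Observed agreement Po in [0, 1].
#' @export
percent_agreement <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("rating matrix must be complete (no missing ratings)")
  if (ncol(m) < 2) stop("need at least 2 raters")
  pairs <- utils::combn(ncol(m), 2)
  agree <- vapply(seq_len(ncol(pairs)), function(j)
    m[, pairs[1, j]] == m[, pairs[2, j]], logical(nrow(m)))
  mean(agree)
}

#' Free-marginal (Randolph) multirater kappa
#'
#' Chance-corrected agreement when raters are not constrained to fixed
#' category frequencies: kappa = (Po - 1/c) / (1 - 1/c) for c categories.
#' With c = 3 its range is [-0.5, 1].
#'
#' @param po Observed agreement in [0, 1] (see [percent_agreement()]).
#' @param n_categories Number of rating categories c (default 3).
#' @return Kappa.
#' @export
free_marginal_kappa <- function(po, n_categories = 3) {
  stopifnot(po >= 0, po <= 1, n_categories >= 2)
  pe <- 1 / n_categories
  (po - pe) / (1 - pe)
}

#' Inter-rater agreement report
#'
#' Convenience wrapper computing, from a collapsed rating matrix, the
#' observed pairwise agreement and the free-marginal kappa.
#'
#' @param ratings Matrix/data frame of collapsed categories (subjects x
#'   raters).
#' @param n_categories Number of categories (default 3).
#' @return List with `n_subjects`, `percent_agreement`, `kappa`.
#' @export
agreement_report <- function(ratings, n_categories = 3) {
  po <- percent_agreement(ratings)
  list(n_subjects = nrow(as.matrix(ratings)),
       percent_agreement = po,
       kappa = free_marginal_kappa(po, n_categories))
}
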