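#' Euclidean k-means on movement embeddings
#'
#' Lloyd's algorithm with k-means++ initialization, best of `n_init`
#' seeded restarts by within-cluster sum of squares. Applied to the
#' fixed-length, time-aligned movement embeddings, time-series k-means
#' reduces to ordinary Euclidean k-means (no warping is needed when every
#' series shares the clock), which is what this implements.
#' Assignment ties break to the lowest cluster index; a cluster emptied
#' during an update is re-seeded at the point farthest from its centroid.
#'
#' @param Z Numeric matrix, one row per trial (rownames kept as ids).
#' @param k Number of clusters, 1 <= k <= nrow(Z).
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts.
#' @param iter_max Lloyd iteration cap per restart.
#' @return List with `assignments` (named integer vector), `centroids`
#'   (k x p), `inertia` (total within-cluster sum of squares).
#' @export
kmeans_fit <- function(Z, k, seed = 1, n_init = 10, iter_max = 100) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (k < 1 || k > n) stop("k must be in [1, n]")
  if (!all(is.finite(Z))) stop("embeddings must be finite")
  set.seed(seed)
  sq <- rowSums(Z^2)
  dist2_to <- function(centers) {
    # n x k squared distances
    outer(sq, rowSums(centers^2), "+") - 2 * Z %*% t(centers)
  }
  best <- NULL
  for (init in seq_len(n_init)) {
    # k-means++ seeding
    centers <- Z[sample.int(n, 1), , drop = FALSE]
    while (nrow(centers) < k) {
      d2 <- pmax(0, apply(dist2_to(centers), 1, min))
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers <- rbind(centers, Z[sample.int(n, 1, prob = prob), ])
    }
    assign_old <- rep(0L, n)
    for (it in seq_len(iter_max)) {
      d2 <- dist2_to(centers)
      assign_new <- max.col(-d2, ties.method = "first")
      for (j in seq_len(k)) {
        members <- which(assign_new == j)
        if (length(members) == 0) {
          # re-seed an empty cluster at the globally farthest point
          far <- which.max(apply(d2, 1, min))
          centers[j, ] <- Z[far, ]
          assign_new[far] <- j
        } else {
          centers[j, ] <- colMeans(Z[members, , drop = FALSE])
        }
      }
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
    }
    d2 <- dist2_to(centers)
    inertia <- sum(pmax(0, d2[cbind(seq_len(n), assign_old)]))
    if (is.null(best) || inertia < best$inertia - 1e-12)
      best <- list(assignments = assign_old, centroids = centers,
                   inertia = inertia)
  }
  names(best$assignments) <- rownames(Z)
  best
}

#' Inertia curve over candidate cluster counts
#'
#' @param Z Embedding matrix.
#' @param k_max Largest k to evaluate (capped at n).
#' @param seed,n_init Passed to [kmeans_fit()].
#' @return Data frame with `k` and `inertia`.
#' @export
inertia_curve <- function(Z, k_max = 8, seed = 1, n_init = 10) {
  ks <- seq_len(min(k_max, nrow(as.matrix(Z))))
  data.frame(k = ks,
             inertia = vapply(ks, function(k)
               kmeans_fit(Z, k, seed = seed, n_init = n_init)$inertia,
               numeric(1)))
}

#' Elbow-point selection of the number of clusters
#'
#' Kneedle-style detector: after min-max normalizing both axes, the
#' selected k maximizes the perpendicular distance from (k, inertia_k) to
#' the chord joining the first and last curve points. A curve with no
#' elbow (maximum distance below `tol`, e.g. exactly linear) returns 1.
#' A non-monotone curve (beyond restart noise) triggers a warning only.
#'
#' @param inertia Numeric inertia values for `k = 1..K`.
#' @param k_values Corresponding k values (default `1..length(inertia)`).
#' @param tol Distance below which no elbow is declared.
#' @return Selected k.
#' @export
elbow_select <- function(inertia, k_values = seq_along(inertia),
                         tol = 1e-6) {
  stopifnot(length(inertia) == length(k_values), all(is.finite(inertia)))
  if (length(inertia) < 3) stop("need the curve over at least 3 values of k")
  if (any(diff(inertia) > 1e-8 * max(abs(inertia))))
    warning("inertia curve is not non-increasing in k")
  x <- (k_values - k_values[1]) / (k_values[length(k_values)] - k_values[1])
  rng <- range(inertia)
  y <- if (diff(rng) > 0) (inertia - rng[1]) / diff(rng) else inertia * 0
  # chord from (x1, y1) to (xK, yK); distance of each point to it
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  num <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1)
  d <- num / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  if (max(d) < tol) return(k_values[1])
  k_values[which.max(d)]
}

#' Screen embedding outliers before clustering
#'
#' Flags trials whose Euclidean distance to the embedding medoid exceeds
#' `median + mult * MAD` of those distances (single pass).
#'
#' @param Z Embedding matrix with trial ids as rownames.
#' @param mult MAD multiplier (default 3.5).
#' @return Character vector of excluded trial ids (possibly empty).
#' @export
detect_outliers <- function(Z, mult = 3.5) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 5) stop("outlier screen needs at least 5 trials")
  dm <- as.matrix(stats::dist(Z))
  medoid <- which.min(rowSums(dm))
  d <- dm[, medoid]
  cut <- stats::median(d) + mult * stats::mad(d)
  ids <- rownames(Z) %||% as.character(seq_len(nrow(Z)))
  ids[d > cut]
}

#' Cross-tabulate cluster assignments against labels
#'
#' @param assignments Named vector (trial_id -> cluster).
#' @param labels Named vector (trial_id -> label, e.g. the majority expert
#'   score).
#' @return A contingency `table` (labels x clusters) with margins.
#' @export
crosstab <- function(assignments, labels) {
  ids <- names(assignments)
  if (is.null(ids) || is.null(names(labels)) ||
      !setequal(ids, names(labels)))
    stop("assignments and labels must cover the same trial ids")
  labels <- labels[ids]
  stats::addmargins(table(score = labels, cluster = assignments))
}

#' Cluster a cohort of movement embeddings
#'
#' The full unsupervised stage: outlier screening, inertia curve over
#' `k = 1..k_max`, elbow selection of k, and the final fit.
#'
#' @param Z Embedding matrix (rownames = trial ids).
#' @param k_max Largest candidate k.
#' @param seed,n_init Passed to [kmeans_fit()].
#' @param outlier_mult MAD multiplier for [detect_outliers()].
#' @return An object of class `clustering_result`: `k_selected`,
#'   `assignments`, `centroids`, `inertia_curve`, `excluded_outliers`,
#'   `seed`.
#' @export
cluster_trials <- function(Z, k_max = 8, seed = 1, n_init = 10,
                           outlier_mult = 3.5) {
  Z <- as.matrix(Z)
  out <- detect_outliers(Z, mult = outlier_mult)
  keep <- setdiff(rownames(Z) %||% as.character(seq_len(nrow(Z))), out)
  Zk <- Z[keep, , drop = FALSE]
  curve <- inertia_curve(Zk, k_max = k_max, seed = seed, n_init = n_init)
  k_star <- elbow_select(curve$inertia, curve$k)
  fit <- kmeans_fit(Zk, k_star, seed = seed, n_init = n_init)
  structure(
    list(k_selected = k_star, assignments = fit$assignments,
         centroids = fit$centroids, inertia_curve = curve,
         excluded_outliers = out, seed = seed),
    class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("<clustering_result> k =", x$k_selected, "over",
      length(x$assignments), "trials;",
      length(x$excluded_outliers), "outlier(s) excluded\n")
  print(table(cluster = x$assignments))
  invisible(x)
}
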