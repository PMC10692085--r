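#' 2-D t-SNE projection normalized to the unit square
#'
#' Exact (dense) t-SNE, adequate for cohort sizes here (tens of trials):
#' Gaussian input affinities with per-point bandwidths calibrated to the
#' target perplexity by bisection, Student-t low-dimensional kernel,
#' gradient descent with momentum and early exaggeration. Output
#' coordinates are min-max normalized to [0, 1] per axis, the convention
#' used for the cluster maps. Deterministic given `seed`; used for
#' visualization only, never for inference.
#'
#' @param Z Embedding matrix (one row per trial).
#' @param seed Integer seed for the random initial layout.
#' @param perplexity Target perplexity; default `min(30, (n - 1) / 3)`.
#' @param n_iter Gradient-descent iterations.
#' @return n x 2 matrix of coordinates in [0, 1]^2 (rownames kept).
#' @export
project_2d <- function(Z, seed = 1, perplexity = NULL, n_iter = 500) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n < 5) stop("need at least 5 points")
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  perplexity <- max(2, min(perplexity, (n - 1) / 3))
  D2 <- as.matrix(stats::dist(Z))^2

  # per-point precision by bisection on entropy
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; bmin <- -Inf; bmax <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1 / length(di), length(di)) else p <- p / sp
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  lr <- 100
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    momentum <- if (it <= 250) 0.5 else 0.8
    inc <- momentum * inc - lr * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rng <- apply(Y, 2, range)
  for (ax in 1:2) {
    span <- rng[2, ax] - rng[1, ax]
    Y[, ax] <- if (span > 0) (Y[, ax] - rng[1, ax]) / span else 0.5
  }
  rownames(Y) <- rownames(Z)
  colnames(Y) <- c("tsne_1", "tsne_2")
  Y
}
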