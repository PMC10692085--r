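#' Autoencoder architecture specification
#'
#' Fixed encoder architecture: 1-D convolution with window size 3 (same
#' padding, ReLU), dropout with p = 0.1, max-pooling with window size 2.
#' The decoder mirrors it: upsample by 2 (repeat) followed by a window-3
#' convolution back to the 4 input channels (linear output). Only the
#' number of filters and the training hyperparameters are tunable; the
#' window sizes and dropout rate are part of the architecture contract
#' and are rejected unless `allow_nonstandard = TRUE`.
#'
#' @param input_length Frames per trial (m_time).
#' @param n_filters Convolution filters in the encoder.
#' @param input_channels Input channels (4: dog_x, dog_y, person_x,
#'   person_y).
#' @param conv_window,dropout_p,pool_window Architecture constants (3,
#'   0.1, 2).
#' @param learning_rate,batch_size,epochs,patience Training
#'   hyperparameters (Adam step size, minibatch size, epoch cap, early
#'   stopping patience in epochs).
#' @param seed Integer seed for weight init, batching and dropout.
#' @param allow_nonstandard Permit non-contract architecture values.
#' @return An object of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(input_length, n_filters = 8,
                             input_channels = 4, conv_window = 3,
                             dropout_p = 0.1, pool_window = 2,
                             learning_rate = 1e-3, batch_size = 8,
                             epochs = 150, patience = 15, seed = 1,
                             allow_nonstandard = FALSE) {
  if (input_length < 4) stop("input_length must be at least 4 frames")
  stopifnot(n_filters >= 1, learning_rate > 0, batch_size >= 1,
            epochs >= 1, patience >= 1)
  if (!allow_nonstandard &&
      (conv_window != 3 || dropout_p != 0.1 || pool_window != 2))
    stop("architecture is fixed at conv_window = 3, dropout_p = 0.1, ",
         "pool_window = 2; set allow_nonstandard = TRUE to override")
  structure(
    list(input_length = as.integer(input_length),
         n_filters = as.integer(n_filters),
         input_channels = as.integer(input_channels),
         conv_window = conv_window, dropout_p = dropout_p,
         pool_window = pool_window, learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         patience = as.integer(patience), seed = as.integer(seed)),
    class = "autoencoder_spec")
}

# ---- array primitives (n x L x C layout throughout) ------------------------

# Y[, t, ] = X[, t + s, ], zero-filled outside [1, L]
shift_time <- function(X, s) {
  if (s == 0) return(X)
  dm <- dim(X); L <- dm[2]
  Y <- array(0, dm)
  if (s > 0) Y[, seq_len(L - s), ] <- X[, (s + 1):L, , drop = FALSE]
  else Y[, (1 - s):L, ] <- X[, seq_len(L + s), , drop = FALSE]
  Y
}

conv1d_forward <- function(X, W, b) {
  dm <- dim(X); n <- dm[1]; L <- dm[2]; Cin <- dm[3]; Cout <- dim(W)[3]
  out <- matrix(b, n * L, Cout, byrow = TRUE)
  for (o in 1:3)
    out <- out + matrix(shift_time(X, o - 2), n * L, Cin) %*%
      matrix(W[o, , ], Cin, Cout)
  array(out, c(n, L, Cout))
}

conv1d_backward <- function(X, W, d_out, need_d_in = TRUE) {
  dm <- dim(X); n <- dm[1]; L <- dm[2]; Cin <- dm[3]; Cout <- dim(W)[3]
  dW <- array(0, dim(W))
  d_out_m <- matrix(d_out, n * L, Cout)
  for (o in 1:3)
    dW[o, , ] <- crossprod(matrix(shift_time(X, o - 2), n * L, Cin), d_out_m)
  db <- colSums(d_out_m)
  d_in <- NULL
  if (need_d_in) {
    d_in <- array(0, c(n, L, Cin))
    for (o in 1:3)
      d_in <- d_in + array(
        matrix(shift_time(d_out, -(o - 2)), n * L, Cout) %*%
          t(matrix(W[o, , ], Cin, Cout)),
        c(n, L, Cin))
  }
  list(dW = dW, db = db, d_in = d_in)
}

maxpool2_forward <- function(X) {
  L <- dim(X)[2]; Lp <- L %/% 2
  a <- X[, seq(1, 2 * Lp, 2), , drop = FALSE]
  b <- X[, seq(2, 2 * Lp, 2), , drop = FALSE]
  keep_first <- a >= b  # ties go to the earlier frame (deterministic)
  list(P = pmax(a, b), keep_first = keep_first)
}

maxpool2_backward <- function(dP, keep_first, L) {
  dm <- dim(dP); Lp <- dm[2]
  dX <- array(0, c(dm[1], L, dm[3]))
  dX[, seq(1, 2 * Lp, 2), ] <- dP * keep_first
  dX[, seq(2, 2 * Lp, 2), ] <- dP * !keep_first
  dX
}

upsample2_forward <- function(P) {
  dm <- dim(P)
  U <- array(0, c(dm[1], 2 * dm[2], dm[3]))
  U[, seq(1, 2 * dm[2], 2), ] <- P
  U[, seq(2, 2 * dm[2], 2), ] <- P
  U
}

upsample2_backward <- function(dU) {
  L2 <- dim(dU)[2]
  dU[, seq(1, L2, 2), , drop = FALSE] + dU[, seq(2, L2, 2), , drop = FALSE]
}

# ---- model -----------------------------------------------------------------

#' Build an (untrained) convolutional autoencoder
#'
#' Initializes He-scaled weights for the fixed architecture described in
#' [autoencoder_spec()]. The latent (movement-space) length per trial is
#' `floor(input_length / 2) * n_filters`; odd input lengths drop the last
#' frame internally so pooling and upsampling mirror exactly.
#'
#' @param spec An [autoencoder_spec()].
#' @return An object of class `conv_autoencoder` (untrained).
#' @export
build_autoencoder <- function(spec) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  set.seed(spec$seed)
  C <- spec$input_channels; F_ <- spec$n_filters
  params <- list(
    W1 = array(stats::rnorm(3 * C * F_, 0, sqrt(2 / (3 * C))), c(3, C, F_)),
    b1 = numeric(F_),
    W2 = array(stats::rnorm(3 * F_ * C, 0, sqrt(2 / (3 * F_))), c(3, F_, C)),
    b2 = numeric(C))
  Lp <- spec$input_length %/% 2L
  structure(
    list(spec = spec, params = params,
         latent_length = Lp * F_,
         effective_length = 2L * Lp,
         standardization = NULL, trained = FALSE),
    class = "conv_autoencoder")
}

#' @export
print.conv_autoencoder <- function(x, ...) {
  cat("<conv_autoencoder> ", x$spec$input_channels, "ch x ",
      x$spec$input_length, " frames -> latent ", x$latent_length,
      " (", x$spec$n_filters, " filters)",
      if (x$trained) " [trained]" else " [untrained]", "\n", sep = "")
  invisible(x)
}

ae_forward <- function(params, X, dropout_p, training) {
  Z1 <- conv1d_forward(X, params$W1, params$b1)
  A1 <- Z1 * (Z1 > 0)
  drop_mask <- NULL
  if (training && dropout_p > 0) {
    drop_mask <- array(
      (stats::runif(length(A1)) >= dropout_p) / (1 - dropout_p), dim(A1))
    A1d <- A1 * drop_mask
  } else A1d <- A1
  pool <- maxpool2_forward(A1d)
  U <- upsample2_forward(pool$P)
  Y <- conv1d_forward(U, params$W2, params$b2)
  list(Z1 = Z1, drop_mask = drop_mask, pool = pool, U = U, Y = Y)
}

ae_backward <- function(params, X, fw) {
  dY <- sign(fw$Y - X) / length(fw$Y)            # d(MAE)/dY
  bw2 <- conv1d_backward(fw$U, params$W2, dY, need_d_in = TRUE)
  dP <- upsample2_backward(bw2$d_in)
  dA1d <- maxpool2_backward(dP, fw$pool$keep_first, dim(X)[2])
  if (!is.null(fw$drop_mask)) dA1d <- dA1d * fw$drop_mask
  dZ1 <- dA1d * (fw$Z1 > 0)
  bw1 <- conv1d_backward(X, params$W1, dZ1, need_d_in = FALSE)
  list(W1 = bw1$dW, b1 = bw1$db, W2 = bw2$dW, b2 = bw2$db)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# MAE between reconstruction and target on the original (meter) scale
ae_mae <- function(params, X, sds) {
  fw <- ae_forward(params, X, dropout_p = 0, training = FALSE)
  err <- abs(fw$Y - X)
  for (c in seq_along(sds)) err[, , c] <- err[, , c] * sds[c]
  mean(err)
}

#' Train the convolutional autoencoder with a hyperparameter grid search
#'
#' Standardizes each channel (z-score over the whole cohort), splits the
#' trials into train/validation sets, and for every grid point trains the
#' fixed architecture with Adam on mean-absolute-error reconstruction
#' loss, with minibatches and early stopping on validation MAE. The grid
#' point with the lowest validation MAE (reported in original units,
#' meters) wins. Fully deterministic given `seed`.
#'
#' @param dataset A `trajectory_dataset` (n >= 4 trials).
#' @param grid Named list of hyperparameter vectors crossed with
#'   `expand.grid`; entries may be `n_filters`, `learning_rate`,
#'   `epochs`, `batch_size`, `patience`.
#' @param seed Integer seed (weights, split, batching, dropout).
#' @param val_fraction Fraction of trials held out for validation.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (trained `conv_autoencoder`, including the
#'   standardization), `log` (per-epoch train/val MAE for every grid
#'   point; epoch 0 is the untrained model), `grid_results`, `selected`.
#' @export
train_autoencoder <- function(dataset,
                              grid = list(n_filters = c(4, 8),
                                          learning_rate = 1e-3),
                              seed = 1, val_fraction = 0.25,
                              verbose = FALSE) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  n <- length(dataset$trial_ids)
  if (n < 4) stop("need at least 4 trials for a train/validation split")
  if (length(grid) == 0 || any(!lengths(grid)))
    stop("hyperparameter grid is empty")
  gridf <- do.call(expand.grid, c(grid, stringsAsFactors = FALSE))
  if (nrow(gridf) == 0) stop("hyperparameter grid is empty")

  # center each channel; scale all channels by one pooled sd so that a
  # near-static channel (the seated person) is not blown up to pure noise
  X <- dataset$array
  mus <- apply(X, 3, mean)
  pooled <- sqrt(mean(apply(X, 3, stats::var)))
  if (pooled < 1e-12) pooled <- 1
  sds <- rep(pooled, dim(X)[3])
  for (c in 1:4) X[, , c] <- (X[, , c] - mus[c]) / sds[c]

  set.seed(seed)
  n_val <- max(1L, round(val_fraction * n))
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)

  logs <- list(); results <- NULL
  best <- NULL
  for (g in seq_len(nrow(gridf))) {
    hp <- as.list(gridf[g, , drop = FALSE])
    spec <- autoencoder_spec(
      input_length = dataset$m_time,
      n_filters = hp$n_filters %||% 8,
      learning_rate = hp$learning_rate %||% 1e-3,
      batch_size = hp$batch_size %||% 8,
      epochs = hp$epochs %||% 150,
      patience = hp$patience %||% 15,
      seed = seed + g)
    model <- build_autoencoder(spec)
    Leff <- model$effective_length
    Xe <- X[, seq_len(Leff), , drop = FALSE]
    Xtr <- Xe[tr_idx, , , drop = FALSE]
    Xval <- Xe[val_idx, , , drop = FALSE]
    params <- model$params
    st <- adam_init(params)
    set.seed(spec$seed)  # batching + dropout stream
    log <- data.frame(grid_point = g, epoch = 0,
                      train_mae = ae_mae(params, Xtr, sds),
                      val_mae = ae_mae(params, Xval, sds))
    best_val <- log$val_mae[1]; best_params <- params; wait <- 0
    for (ep in seq_len(spec$epochs)) {
      perm <- sample(seq_along(tr_idx))
      starts <- seq(1, length(perm), by = spec$batch_size)
      for (s in starts) {
        bi <- perm[s:min(s + spec$batch_size - 1, length(perm))]
        Xb <- Xtr[bi, , , drop = FALSE]
        fw <- ae_forward(params, Xb, spec$dropout_p, training = TRUE)
        gr <- ae_backward(params, Xb, fw)
        up <- adam_step(params, gr, st, spec$learning_rate)
        params <- up$params; st <- up$state
      }
      tm <- ae_mae(params, Xtr, sds); vm <- ae_mae(params, Xval, sds)
      log <- rbind(log, data.frame(grid_point = g, epoch = ep,
                                   train_mae = tm, val_mae = vm))
      if (verbose) message(sprintf("grid %d epoch %d train %.4f val %.4f",
                                   g, ep, tm, vm))
      if (vm < best_val - 1e-9) {
        best_val <- vm; best_params <- params; wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= spec$patience) break
      }
    }
    logs[[g]] <- log
    results <- rbind(results,
                     data.frame(grid_point = g, gridf[g, , drop = FALSE],
                                val_mae = best_val, row.names = NULL))
    if (is.null(best) || best_val < best$val_mae) {
      model$params <- best_params
      model$standardization <- list(mu = mus, sd = sds)
      model$trained <- TRUE
      best <- list(model = model, val_mae = best_val, grid_point = g)
    }
  }
  list(model = best$model, log = do.call(rbind, logs),
       grid_results = results,
       selected = results[results$grid_point == best$grid_point, ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode trials into the movement space
#'
#' Runs the trained encoder (convolution + ReLU + max-pooling; dropout
#' inactive at inference) on each trial and flattens the pooled feature
#' maps into one embedding vector per trial. Deterministic.
#'
#' @param model A trained `conv_autoencoder`.
#' @param dataset A `trajectory_dataset` whose `m_time` matches the model.
#' @return Numeric matrix, one row per trial (rownames = trial ids), with
#'   `floor(m_time / 2) * n_filters` columns.
#' @export
encode <- function(model, dataset) {
  stopifnot(inherits(model, "conv_autoencoder"))
  if (!model$trained) stop("model is not trained")
  if (dataset$m_time != model$spec$input_length)
    stop("dataset length ", dataset$m_time,
         " does not match model input_length ", model$spec$input_length)
  X <- dataset$array
  std <- model$standardization
  for (c in 1:4) X[, , c] <- (X[, , c] - std$mu[c]) / std$sd[c]
  Xe <- X[, seq_len(model$effective_length), , drop = FALSE]
  Z1 <- conv1d_forward(Xe, model$params$W1, model$params$b1)
  A1 <- Z1 * (Z1 > 0)
  P <- maxpool2_forward(A1)$P
  Z <- matrix(P, nrow = dim(P)[1])
  rownames(Z) <- dataset$trial_ids
  Z
}
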