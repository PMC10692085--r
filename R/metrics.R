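#' Classification metrics (accuracy, macro precision/recall/F1)
#'
#' Accuracy is the fraction of correct predictions. Precision, recall and
#' F1 are computed per class (over the classes present in `y_true`) and
#' macro-averaged; an undefined per-class ratio (empty denominator)
#' counts as 0.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @return List with `accuracy`, `precision`, `recall`, `f1`.
#' @export
evaluate_classifier <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  classes <- sort(unique(y_true))
  per <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, numeric(3))
  list(accuracy = mean(y_true == y_pred),
       precision = mean(per[1, ]), recall = mean(per[2, ]),
       f1 = mean(per[3, ]))
}

#' Regression metrics (MAE, MSE, R-squared)
#'
#' @param y_true,y_pred Numeric vectors of equal length (n >= 2).
#' @return List with `mae`, `mse`, `r2`. `r2` is `NA` (with a warning)
#'   when `y_true` has zero variance.
#' @export
evaluate_regressor <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (length(y_true) < 2) stop("need at least 2 observations")
  e <- y_pred - y_true
  sstot <- sum((y_true - mean(y_true))^2)
  r2 <- if (sstot > 0) 1 - sum(e^2) / sstot else {
    warning("y_true has zero variance; R-squared undefined")
    NA_real_
  }
  list(mae = mean(abs(e)), mse = mean(e^2), r2 = r2)
}
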