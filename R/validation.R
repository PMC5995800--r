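# Nonparametric agreement and classification diagnostics.

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). On tie-free data this equals the classical closed form
#' `1 - 6 * sum(d^2) / (n * (n^2 - 1))`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("inputs must be finite")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stopf("rank variance is zero; Spearman correlation undefined")
  }
  stats::cor(rx, ry)
}

#' Confusion-matrix diagnostics for a binary classifier
#'
#' Sensitivity is taken with respect to class 1 (active).
#'
#' @param y_true,y_pred binary vectors (0/1) of equal length.
#' @return a `validation_report` list: `n`, `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("y_true and y_pred must have equal length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stopf("inputs must be binary 0/1")
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  n <- length(y_true)
  structure(
    list(n = n, tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / n,
         sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("n = %d  TP %d  FP %d  TN %d  FN %d\n", x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("accuracy %.3f  sensitivity %.3f  specificity %.3f", x$accuracy,
              x$sensitivity, x$specificity))
  if (!is.null(x$spearman_rho)) cat(sprintf("  spearman rho %.3f", x$spearman_rho))
  cat("\n")
  invisible(x)
}

#' Validate a model's activity estimates against experiment
#'
#' Correlates the model-derived estimate (predicted probability of the
#' active class by default, or the hard label) with the experimental
#' binary class via Spearman's rho, and reports confusion diagnostics of
#' the hard labels.
#'
#' @param model an `iopqsar_mlp`.
#' @param X predictor matrix.
#' @param y experimental binary class.
#' @param use `"prob"` (default) or `"class"`: which estimate enters the
#'   rank correlation.
#' @return a `validation_report` with `spearman_rho` added.
#' @export
validate_model <- function(model, X, y, use = c("prob", "class")) {
  use <- match.arg(use)
  y <- as.integer(y)
  pred_class <- predict(model, X, type = "class")
  est <- if (use == "prob") predict(model, X, type = "prob")[, "class1"] else pred_class
  rep <- confusion_metrics(y, pred_class)
  rep$spearman_rho <- spearman_rho(as.numeric(est), as.numeric(y))
  rep$estimate <- use
  rep
}

#' Adjusted Rand index between two partitions
#'
#' Thin wrapper over [mclust::adjustedRandIndex()], exposed so clustering
#' recovery can be scored without attaching mclust.
#'
#' @param a,b cluster label vectors of equal length.
#' @return the chance-corrected Rand agreement.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions must have equal length")
  mclust::adjustedRandIndex(a, b)
}
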