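#' Balanced classification rate
#'
#' BCR combines sensitivity and specificity while penalizing their
#' imbalance: `BCR = ((Se + Sp) / 2) * (1 - |Se - Sp|)`.  It equals the
#' usual balanced accuracy only when Se = Sp, and drops to 0 when one of
#' the two rates collapses.
#'
#' @param se Sensitivity (true-positive rate) in `[0, 1]`.
#' @param sp Specificity (true-negative rate) in `[0, 1]`.
#' @return A numeric value in `[0, 1]`.
#' @examples
#' bcr(1, 1)          # 1
#' bcr(0.961, 0.988)  # 0.94819...
#' @export
bcr <- function(se, sp) {
  check_prob(se, "sensitivity")
  check_prob(sp, "specificity")
  ((se + sp) / 2) * (1 - abs(se - sp))
}

#' Ensemble diversity entropy
#'
#' Non-pairwise diversity of a classifier ensemble.  For each instance i
#' let `theta_i` be the number of the T classifiers that misclassify it;
#' then `E = mean( min(theta_i, T - theta_i) / (T - ceiling(T / 2)) )`.
#' E is 0 when all classifiers behave identically on every instance and 1
#' when disagreement is maximal (each instance splits the ensemble as
#' evenly as possible).
#'
#' @param pred_matrix N x T matrix of binary (0/1) predictions, one column
#'   per classifier.
#' @param y Length-N vector of true 0/1 labels.
#' @return Entropy E in `[0, 1]`.
#' @export
ensemble_entropy <- function(pred_matrix, y) {
  pred_matrix <- as.matrix(pred_matrix)
  if (nrow(pred_matrix) != length(y)) {
    stop_hs("pred_matrix has %d rows but y has %d labels",
            nrow(pred_matrix), length(y))
  }
  T_ <- ncol(pred_matrix)
  if (T_ < 2L) stop_hs("ensemble_entropy needs at least 2 classifiers")
  if (!all(pred_matrix %in% c(0, 1))) stop_hs("predictions must be binary 0/1")
  theta <- rowSums(pred_matrix != y)
  mean(pmin(theta, T_ - theta)) / (T_ - ceiling(T_ / 2))
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed from mid-ranks; tied scores
#' contribute 1/2 per positive-negative pair.
#'
#' @param y_true 0/1 labels.
#' @param proba Scores (higher = more positive).
#' @return AUC in `[0, 1]`, or `NA` (with a warning) if only one class is
#'   present.
#' @export
auc_mw <- function(y_true, proba) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(proba)) stop_hs("length mismatch in auc_mw")
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(proba, ties.method = "average")
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' Computes accuracy, sensitivity, specificity, rank-based AUC and BCR at
#' a probability cut.  Scores exactly at the cut are called positive.
#'
#' @param y_true 0/1 labels.
#' @param proba Positive-class probabilities.
#' @param cut Decision threshold (default 0.5).
#' @return An object of class `"classification_metrics"`: a list with
#'   elements `accuracy`, `sensitivity`, `specificity`, `auc`, `bcr`,
#'   `n`, `cut`.
#' @export
classification_metrics <- function(y_true, proba, cut = 0.5) {
  y_true <- as.integer(y_true)
  check_prob(proba, "proba")
  if (length(y_true) != length(proba)) stop_hs("length mismatch")
  pred <- as.integer(proba >= cut)
  tp <- sum(pred == 1L & y_true == 1L)
  tn <- sum(pred == 0L & y_true == 0L)
  fp <- sum(pred == 1L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  se <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  out <- list(
    accuracy    = (tp + tn) / length(y_true),
    sensitivity = se,
    specificity = sp,
    auc         = if (tp + fn > 0L && tn + fp > 0L) auc_mw(y_true, proba) else NA_real_,
    bcr         = if (!is.na(se) && !is.na(sp)) bcr(se, sp) else NA_real_,
    n           = length(y_true),
    cut         = cut
  )
  class(out) <- "classification_metrics"
  out
}

#' @export
print.classification_metrics <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Classification metrics (n = %d, cut = %g):\n  accuracy %s  Se %s  Sp %s  AUC %s  BCR %s\n",
    x$n, x$cut,
    format(x$accuracy, digits = digits), format(x$sensitivity, digits = digits),
    format(x$specificity, digits = digits), format(x$auc, digits = digits),
    format(x$bcr, digits = digits)))
  invisible(x)
}
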