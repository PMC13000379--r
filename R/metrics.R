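check_binary_truth <- function(y) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("truth must be binary 0/1", call. = FALSE)
}

#' Area under the ROC curve (midrank statistic)
#'
#' Computed from the rank-sum of positive-class scores with midranks for
#' ties — equivalent to the probability of concordance with ties counted
#' one half. Undefined (an error, never a silent 0.5) when only one class
#' is present.
#'
#' @param y Binary truth.
#' @param p Scores (any monotone scale).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(y, p) {
  check_binary_truth(y)
  stopifnot(length(y) == length(p))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUROC undefined: a single class is present", call. = FALSE)
  }
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step-wise integration)
#'
#' Average precision: thresholds descend over the distinct score values and
#' each recall increment is weighted by the precision attained there.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(y, p) {
  check_binary_truth(y)
  stopifnot(length(y) == length(p))
  n1 <- sum(y == 1)
  if (n1 == 0 || n1 == length(y)) {
    stop("AUPRC undefined: a single class is present", call. = FALSE)
  }
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]
  ps <- p[ord]
  keep <- c(ps[-length(ps)] != ps[-1], TRUE)  # threshold group boundaries
  tp <- cumsum(ys)[keep]
  fp <- cumsum(1 - ys)[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' Binary classification metrics
#'
#' AUROC (midrank), AUPRC (step-wise), accuracy and F1 at the 0.5
#' threshold. F1 is defined as 0 when no positive is predicted or present.
#'
#' @param y Binary truth.
#' @param p Probabilistic scores.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list `auroc`, `auprc`, `accuracy`, `f1`.
#' @export
binary_metrics <- function(y, p, threshold = 0.5) {
  check_binary_truth(y)
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(auroc = auroc(y, p), auprc = auprc(y, p),
       accuracy = mean(pred == y), f1 = f1)
}

#' Multilabel classification metrics
#'
#' Hamming loss (fraction of wrong label-instance cells at threshold 0.5),
#' subset accuracy (fraction of rows with every label correct), Jaccard
#' index (row-wise intersection over union of predicted and true label
#' sets; rows where both sets are empty score 1), and micro / macro AUROC
#' and AUPRC (micro over the flattened label-instance pairs, macro as the
#' unweighted label-wise mean).
#'
#' @param Y Binary truth matrix (instances x labels).
#' @param P Probability matrix, same shape.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list of the seven metrics.
#' @export
multilabel_metrics <- function(Y, P, threshold = 0.5) {
  Y <- as.matrix(Y)
  P <- as.matrix(P)
  if (!all(dim(Y) == dim(P))) stop("shape mismatch between Y and P", call. = FALSE)
  pred <- (P >= threshold) * 1L
  inter <- rowSums(pred == 1 & Y == 1)
  uni <- rowSums(pred == 1 | Y == 1)
  jac <- ifelse(uni == 0, 1, inter / uni)
  list(
    hamming_loss = mean(pred != Y),
    subset_accuracy = mean(rowSums(pred == Y) == ncol(Y)),
    jaccard = mean(jac),
    micro_auroc = auroc(as.vector(Y), as.vector(P)),
    micro_auprc = auprc(as.vector(Y), as.vector(P)),
    macro_auroc = mean(vapply(seq_len(ncol(Y)), function(j) auroc(Y[, j], P[, j]),
                              numeric(1))),
    macro_auprc = mean(vapply(seq_len(ncol(Y)), function(j) auprc(Y[, j], P[, j]),
                              numeric(1)))
  )
}

#' Calibration metrics: Brier score and expected calibration error
#'
#' Brier is the mean squared probability error. ECE partitions \[0, 1\]
#' into `n_bins` equal-width probability bins and sums, over non-empty
#' bins, the bin weight times the absolute gap between bin accuracy
#' (observed event rate) and bin confidence (mean predicted probability).
#'
#' @param y Binary truth.
#' @param p Predicted probabilities in \[0, 1\].
#' @param n_bins Number of equal-width bins (default 10).
#' @return Named list `brier`, `ece`.
#' @export
calibration_metrics <- function(y, p, n_bins = 10L) {
  check_binary_truth(y)
  stopifnot(length(y) == length(p), n_bins >= 1)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  bin <- cut(p, breaks = seq(0, 1, length.out = n_bins + 1), include.lowest = TRUE)
  acc <- tapply(y, bin, mean)
  conf <- tapply(p, bin, mean)
  w <- tapply(p, bin, length) / length(p)
  keep <- !is.na(acc)
  list(brier = mean((p - y)^2),
       ece = sum(w[keep] * abs(acc[keep] - conf[keep])))
}
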