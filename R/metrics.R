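#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention that any zero factor in the denominator (e.g. all predictions
#' in one class) yields 0 — the "reliable" MCC used for model selection.
#'
#' @param TP,FP,TN,FN confusion counts.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FP + TN + FN > 0)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den)
}

#' Classification accuracy
#'
#' @inheritParams mcc
#' @return (TP + TN) / total.
#' @export
accuracy <- function(TP, FP, TN, FN) {
  total <- TP + FP + TN + FN
  if (total == 0) stop("no observations")
  (TP + TN) / total
}

confusion_counts <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  c(TP = sum(pred & truth), FP = sum(pred & !truth),
    TN = sum(!pred & !truth), FN = sum(!pred & truth))
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with average-rank tie
#' correction; ROC points by sweeping every distinct score as a threshold
#' (prediction: score >= threshold).
#'
#' @param scores numeric scores, larger = more tumor-reactive.
#' @param labels binary truth (`tumor_reactive`/TRUE = positive).
#' @return list with `auc` and `points` (data.frame threshold, tpr, fpr).
#' @export
roc_auc <- function(scores, labels) {
  pos <- group_split(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(tau) {
    pred <- scores >= tau
    c(tpr = sum(pred & pos) / n1, fpr = sum(pred & !pos) / n0)
  }, numeric(2)))
  list(auc = auc,
       points = data.frame(threshold = thr, tpr = pts[, "tpr"],
                           fpr = pts[, "fpr"]))
}

#' Jaccard index of two gene sets
#'
#' Intersection over union after removing duplicates; two empty sets give 0.
#'
#' @param genesA,genesB character vectors.
#' @return real in [0, 1].
#' @export
jaccard <- function(genesA, genesB) {
  a <- unique(genesA); b <- unique(genesB)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}
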