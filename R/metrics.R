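#' @noRd
auc_rank <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)           # average ranks handle ties (Mann-Whitney)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall step curve (no interpolation):
# thresholds sweep the distinct scores from high to low; the area is
# sum over threshold steps of (delta recall) * precision.
#' @noRd
auprc_step <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  if (n1 == 0L || n1 == length(labels)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  last <- which(c(diff(s) != 0, TRUE))   # end of each tied block
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Six-metric evaluation of probabilistic predictions
#'
#' Computes the evaluation suite used throughout the package: AUPRC
#' (area under the precision-recall step curve; the primary metric),
#' AUC (Mann-Whitney rank statistic), and the threshold metrics
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' `F1 = 2PR/(P+R)` and Matthews correlation
#' `(TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A prediction is called positive when `score >= threshold`. MCC and F1
#' are defined as 0 when a denominator vanishes. With single-class
#' labels the ranking metrics are `NA` (with a warning); threshold
#' metrics are still returned.
#'
#' @param scores numeric probabilities in `[0, 1]`.
#' @param labels binary 0/1 labels (1 = positive/moonlighting).
#' @param threshold decision threshold (default 0.5).
#' @return object of class `pmp_metrics`: a list with `auprc`, `auc`,
#'   `sensitivity`, `specificity`, `mcc`, `f1`, `precision`, the
#'   confusion counts and `threshold`.
#' @examples
#' compute_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), length(labels) >= 1L)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  sen <- if (tp + fn > 0) tp / (tp + fn) else 0
  spe <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sen > 0) 2 * prec * sen / (prec + sen) else 0
  mcc_den <- as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den > 0) {
    (as.double(tp) * tn - as.double(fp) * fn) / sqrt(mcc_den)
  } else 0
  if (length(unique(labels)) < 2L) {
    warning("single-class labels: AUC/AUPRC undefined, returned as NA")
  }
  structure(list(auprc = auprc_step(scores, labels),
                 auc = auc_rank(scores, labels),
                 sensitivity = sen, specificity = spe,
                 mcc = mcc, f1 = f1, precision = prec,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 threshold = threshold,
                 n = length(labels), n_pos = sum(labels == 1L)),
            class = "pmp_metrics")
}

#' @export
print.pmp_metrics <- function(x, digits = 4, ...) {
  cat("AUPRC ", format(round(x$auprc, digits)),
      "  AUC ", format(round(x$auc, digits)),
      "  Sen ", format(round(x$sensitivity, digits)),
      "  Spe ", format(round(x$specificity, digits)),
      "  MCC ", format(round(x$mcc, digits)),
      "  F1 ", format(round(x$f1, digits)),
      "  (threshold ", x$threshold, ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @noRd
metrics_row <- function(m) {
  data.frame(auprc = m$auprc, auc = m$auc, sensitivity = m$sensitivity,
             specificity = m$specificity, mcc = m$mcc, f1 = m$f1)
}

#' Stratified k-fold assignment
#'
#' Partitions samples into `k` folds whose sizes differ by at most one,
#' with each class spread across folds within one sample of its global
#' ratio. Deterministic for a given seed.
#'
#' @param labels binary 0/1 labels.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, one per sample.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (any(table(labels) < k)) {
    stop("each class must have at least k = ", k, " members")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}
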