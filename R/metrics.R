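#' Classifier evaluation metrics from a confusion table
#'
#' Sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP), accuracy
#' AC = (TP+TN)/(TP+FP+TN+FN) and the Matthews correlation coefficient
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)), all expressed
#' as percentages. A zero factor in the MCC denominator yields MCC = 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts; alternatively `tp` may
#'   be a named vector/list with elements `tp`, `tn`, `fp`, `fn`.
#' @return Named numeric vector `c(SN, SP, AC, MCC)` in percent.
#' @examples
#' computeMetrics(43, 43, 0, 0)   # all-correct: 100/100/100/100
#' computeMetrics(1, 1, 1, 1)     # chance level: AC 50, MCC 0
#' @export
computeMetrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn)) {
    cc <- as.list(tp); tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || anyNA(counts)) stop("invalid confusion counts")
  if (sum(counts) == 0) stop("all-zero confusion table")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ac <- (tp + tn) / sum(counts)
  den <- prod(c(tp + fn, tn + fp, tp + fp, tn + fn))
  mcc <- if (den == 0) 0 else (tp * tn - fn * fp) / sqrt(den)
  c(SN = 100 * sn, SP = 100 * sp, AC = 100 * ac, MCC = 100 * mcc)
}

confusionFromCalls <- function(predPos, labels) {
  pos <- labels == "pos"
  c(tp = sum(predPos & pos), tn = sum(!predPos & !pos),
    fp = sum(predPos & !pos), fn = sum(!predPos & pos))
}

#' Cross-validation protocol for a given positive-set size
#'
#' Four-fold cross-validation when the positive set has at least 20 members,
#' leave-one-out otherwise.
#'
#' @param nPos Number of positive training sequences.
#' @return `"4-fold"` or `"LOO"`.
#' @export
chooseCvProtocol <- function(nPos) if (nPos >= 20) "4-fold" else "LOO"

# Fold assignment: k roughly equal folds over n items, shuffled under seed.
makeFolds <- function(n, k, seed = NULL) {
  withSeed(seed, {
    idx <- sample.int(n)
    unname(split(idx, rep(seq_len(k), length.out = n)))
  })
}
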