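# SVM domain classifiers over Smith-Waterman alignment-score features
# (libSVM via e1071, RBF kernel), with the grid-search and cross-validation
# protocol used to pick kernel parameters.

#' @importFrom e1071 svm
NULL

#' Default RBF-kernel parameter grid
#'
#' Cost C in 2^-5 ... 2^15 and kernel width r (gamma) in 2^-15 ... 2^3, in
#' powers of four — the conventional libSVM coarse grid.
#'
#' @return `data.frame` with columns `C` and `gamma`.
#' @export
defaultSvmGrid <- function() {
  expand.grid(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2),
              KEEP.OUT.ATTRS = FALSE)
}

# Raw local-alignment score matrix: one row per query, one column per
# reference sequence.
rawScoreMatrix <- function(seqs, refs, matrix = "BLOSUM62", gapOpen = 11,
                           gapExtend = 1) {
  seqs <- Biostrings::AAStringSet(seqs)
  refs <- Biostrings::AAStringSet(refs)
  out <- t(vapply(as.character(seqs), function(s) {
    unname(localScores(s, refs, matrix = matrix, gapOpen = gapOpen,
                       gapExtend = gapExtend))
  }, numeric(length(refs))))
  dimnames(out) <- list(names(seqs), names(refs))
  out
}

#' Alignment-score feature vectors for SVM classification
#'
#' Component i of a query's feature vector is its Smith-Waterman local
#' alignment score against reference sequence i, divided by that reference's
#' self-alignment score (so components lie roughly in [0, 1] and length bias
#' is removed). The reference order is fixed at training time.
#'
#' @param seqs Named `AAStringSet` (or character vector) of queries.
#' @param refs Named `AAStringSet` of reference sequences defining the
#'   feature dimensions, in order.
#' @param refSelf Optional precomputed self-scores of `refs`.
#' @inheritParams alignLocal
#' @return Numeric matrix, queries in rows, `length(refs)` columns.
#' @export
featureVectors <- function(seqs, refs, refSelf = NULL, matrix = "BLOSUM62",
                           gapOpen = 11, gapExtend = 1) {
  refs <- Biostrings::AAStringSet(refs)
  if (is.null(refSelf)) {
    refSelf <- vapply(as.character(refs), function(s) {
      unname(localScores(s, Biostrings::AAStringSet(c(self = s)),
                         matrix = matrix, gapOpen = gapOpen,
                         gapExtend = gapExtend))
    }, 0)
    names(refSelf) <- names(refs)
  }
  raw <- rawScoreMatrix(seqs, refs, matrix = matrix, gapOpen = gapOpen,
                        gapExtend = gapExtend)
  sweep(raw, 2, refSelf, "/")
}

svmFit <- function(features, labels, C, gamma) {
  svm(features, factor(labels, levels = c("neg", "pos")),
      type = "C-classification", kernel = "radial", cost = C, gamma = gamma,
      scale = FALSE)
}

svmPredict <- function(fit, features) {
  p <- predict(fit, features, decision.values = TRUE)
  d <- drop(attr(p, "decision.values"))
  dn <- colnames(attr(p, "decision.values"))[1]
  if (!startsWith(dn, "pos")) d <- -d
  list(positive = unname(p == "pos"), decision = unname(d))
}

# One cross-validation pass over a normalized score matrix. Feature columns
# are restricted to each fold's training sequences so held-out sequences
# never define feature dimensions.
cvSvmOnce <- function(normMatrix, labels, C, gamma, protocol, seed) {
  posIdx <- which(labels == "pos"); negIdx <- which(labels == "neg")
  parts <- withSeed(seed, {
    if (protocol == "4-fold") {
      fp <- makeFolds(length(posIdx), 4)
      fn <- makeFolds(length(negIdx), 4)
      list(active = c(posIdx, negIdx),
           folds = lapply(seq_len(4),
                          function(k) c(posIdx[fp[[k]]], negIdx[fn[[k]]])))
    } else {
      # leave-one-out over positives; negatives resampled 1:1 per repeat
      negs <- sample(negIdx, min(length(posIdx), length(negIdx)))
      list(active = c(posIdx, negs),
           folds = lapply(seq_along(posIdx), function(i) {
             c(posIdx[i], if (i <= length(negs)) negs[i])
           }))
    }
  })
  pred <- logical(0); truth <- character(0)
  for (test in parts$folds) {
    train <- setdiff(parts$active, test)
    fit <- svmFit(normMatrix[train, train, drop = FALSE], labels[train],
                  C, gamma)
    out <- svmPredict(fit, normMatrix[test, train, drop = FALSE])
    pred <- c(pred, out$positive); truth <- c(truth, labels[test])
  }
  computeMetrics(confusionFromCalls(pred, truth))
}

cvSvmRepeats <- function(normMatrix, labels, C, gamma, repeats, seed) {
  protocol <- chooseCvProtocol(sum(labels == "pos"))
  per <- t(vapply(seq_len(repeats), function(r) {
    cvSvmOnce(normMatrix, labels, C, gamma, protocol, seed + r)
  }, numeric(4)))
  list(metrics = colMeans(per), perRepeat = as.data.frame(per),
       protocol = protocol)
}

#' Cross-validate an SVM domain classifier
#'
#' Four-fold cross-validation when there are at least 20 positives,
#' leave-one-out otherwise; metrics are averaged over `repeats` repetitions
#' (leave-one-out repetitions differ only through negative resampling when
#' the negative set is larger than the positive set).
#'
#' @param positives,negatives Named `AAStringSet`s of training sequences.
#' @param C,gamma RBF kernel parameters.
#' @param repeats Number of repeated cross-validations to average.
#' @param seed Integer seed controlling folds and resampling.
#' @inheritParams alignLocal
#' @return List with `metrics` (mean `SN`/`SP`/`AC`/`MCC`, percent),
#'   `perRepeat` and `protocol`.
#' @export
crossValidateSvm <- function(positives, negatives, C = 1, gamma = 0.01,
                             repeats = 10, seed = 42, matrix = "BLOSUM62",
                             gapOpen = 11, gapExtend = 1) {
  positives <- Biostrings::AAStringSet(positives)
  negatives <- Biostrings::AAStringSet(negatives)
  all <- c(positives, negatives)
  labels <- rep(c("pos", "neg"), c(length(positives), length(negatives)))
  raw <- rawScoreMatrix(all, all, matrix = matrix, gapOpen = gapOpen,
                        gapExtend = gapExtend)
  norm <- sweep(raw, 2, diag(raw), "/")
  cvSvmRepeats(norm, labels, C, gamma, repeats, seed)
}

#' Train a subfamily SVM with grid-searched kernel parameters
#'
#' Scans the (C, gamma) grid by cross-validation and selects the pair
#' maximizing the mean product of sensitivity and specificity; ties are
#' broken by the smaller C, then the smaller gamma. The final model is
#' refit on all training data at the winning parameters. Feature dimensions
#' are the training sequences themselves (positives then negatives), with
#' per-dimension normalization by the reference self-score.
#'
#' @inheritParams crossValidateSvm
#' @param grid `data.frame` of candidate `C`/`gamma` pairs
#'   (default [defaultSvmGrid()]).
#' @param repeats Cross-validation repeats used during selection.
#' @return List (class `"t2pksSvm"`) with the fitted `e1071` model, the
#'   reference order and self-scores, selected `C`/`gamma`, the grid search
#'   table and the winning cross-validation metrics.
#' @export
trainSvm <- function(positives, negatives, grid = defaultSvmGrid(),
                     repeats = 3, seed = 42, matrix = "BLOSUM62",
                     gapOpen = 11, gapExtend = 1) {
  positives <- Biostrings::AAStringSet(positives)
  negatives <- Biostrings::AAStringSet(negatives)
  if (length(positives) < 2 || length(negatives) < 1) {
    stop("trainSvm needs at least 2 positives and 1 negative")
  }
  all <- c(positives, negatives)
  stopifnot(!anyDuplicated(names(all)))
  labels <- rep(c("pos", "neg"), c(length(positives), length(negatives)))
  raw <- rawScoreMatrix(all, all, matrix = matrix, gapOpen = gapOpen,
                        gapExtend = gapExtend)
  refSelf <- diag(raw)
  norm <- sweep(raw, 2, refSelf, "/")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cv <- cvSvmRepeats(norm, labels, grid$C[i], grid$gamma[i], repeats,
                       seed + 977L * i)
    c(C = grid$C[i], gamma = grid$gamma[i],
      product = unname(cv$metrics["SN"] * cv$metrics["SP"] / 1e4),
      cv$metrics)
  })
  res <- as.data.frame(do.call(rbind, res))
  ord <- order(-res$product, res$C, res$gamma)
  best <- res[ord[1], ]
  fit <- svmFit(norm, labels, best$C, best$gamma)
  structure(list(fit = fit, refIds = names(all),
                 refSeqs = as.character(all), refSelf = refSelf,
                 C = best$C, gamma = best$gamma,
                 cvMetrics = unlist(best[c("SN", "SP", "AC", "MCC")]),
                 protocol = chooseCvProtocol(length(positives)),
                 grid = res, matrix = matrix, gapOpen = gapOpen,
                 gapExtend = gapExtend, seed = seed),
            class = "t2pksSvm")
}

# Decision values of an SVM model on new sequences (positive value = call).
svmClassify <- function(model, seqs) {
  feats <- featureVectors(seqs, Biostrings::AAStringSet(
    stats::setNames(model$refSeqs, model$refIds)),
    refSelf = model$refSelf, matrix = model$matrix,
    gapOpen = model$gapOpen, gapExtend = model$gapExtend)
  out <- svmPredict(model$fit, feats)
  data.frame(seq_id = rownames(feats), positive = out$positive,
             decision = out$decision, stringsAsFactors = FALSE)
}
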