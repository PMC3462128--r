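# Cross-validation of profile-HMM classifiers under the same fold protocol
# as the SVM: 4-fold when the positive set has >= 20 members, leave-one-out
# otherwise, averaged over repeats.

cvHmmOnce <- function(msa, members, negatives, margin, protocol, seed) {
  npos <- length(members)
  parts <- withSeed(seed, {
    if (protocol == "4-fold") {
      fp <- makeFolds(npos, 4)
      fn <- makeFolds(length(negatives), 4)
      list(folds = lapply(seq_len(4), function(k) {
        list(testPos = fp[[k]], testNeg = fn[[k]])
      }))
    } else {
      negs <- sample(length(negatives), min(npos, length(negatives)))
      list(folds = lapply(seq_len(npos), function(i) {
        list(testPos = i, testNeg = if (i <= length(negs)) negs[i])
      }))
    }
  })
  # one profile per fold, trained on the held-in rows of the shared MSA;
  # all profiles are then scored against all test sequences in one pass
  profiles <- lapply(seq_along(parts$folds), function(k) {
    trainRows <- setdiff(seq_len(npos), parts$folds[[k]]$testPos)
    p <- buildProfile(msa[trainRows], name = paste0("fold_", k),
                      margin = margin)
    p
  })
  testSeqs <- c(members, negatives)
  scores <- scoreProfiles(profiles, testSeqs)
  pred <- logical(0); truth <- character(0)
  for (k in seq_along(parts$folds)) {
    f <- parts$folds[[k]]
    thr <- profiles[[k]]$threshold
    testIds <- c(names(members)[f$testPos], names(negatives)[f$testNeg])
    lab <- rep(c("pos", "neg"), c(length(f$testPos), length(f$testNeg)))
    sc <- scores[scores$profile == paste0("fold_", k), ]
    bits <- stats::setNames(rep(-Inf, length(testIds)), testIds)
    hit <- intersect(testIds, sc$seq_id)
    bits[hit] <- sc$bits[match(hit, sc$seq_id)]
    pred <- c(pred, bits >= thr); truth <- c(truth, lab)
  }
  computeMetrics(confusionFromCalls(pred, truth))
}

#' Cross-validate a profile-HMM domain classifier
#'
#' Builds one multiple alignment of the positive set, then per fold trains a
#' profile on the held-in rows, calibrates its threshold on the held-in
#' members, and tests the held-out positives and negatives. The protocol is
#' four-fold for at least 20 positives, leave-one-out otherwise;
#' leave-one-out repetitions differ only through negative resampling.
#'
#' @param positives,negatives Named `AAStringSet`s.
#' @param margin Calibration margin in bits (see [buildProfile()]).
#' @param repeats Repetitions to average.
#' @param seed Integer seed.
#' @return List with `metrics` (mean `SN`/`SP`/`AC`/`MCC`), `perRepeat`
#'   and `protocol`.
#' @export
crossValidateHmm <- function(positives, negatives, margin = 10, repeats = 10,
                             seed = 42) {
  positives <- Biostrings::AAStringSet(positives)
  negatives <- Biostrings::AAStringSet(negatives)
  stopifnot(length(positives) >= 2)
  protocol <- chooseCvProtocol(length(positives))
  msa <- buildMsa(positives)
  per <- t(vapply(seq_len(repeats), function(r) {
    cvHmmOnce(msa, positives, negatives, margin, protocol, seed + r)
  }, numeric(4)))
  list(metrics = colMeans(per), perRepeat = as.data.frame(per),
       protocol = protocol)
}

#' Cross-validate a domain classifier of either type
#'
#' Dispatcher over [crossValidateHmm()] and [crossValidateSvm()] with the
#' shared protocol rule (4-fold iff at least 20 positives, else
#' leave-one-out) and 10 repetitions by default.
#'
#' @param type `"HMM"` or `"SVM"`.
#' @param positives,negatives Named `AAStringSet`s.
#' @param repeats Repetitions to average (default 10).
#' @param seed Integer seed.
#' @param ... Passed to the type-specific routine (`margin`; `C`, `gamma`).
#' @return List with `metrics`, `perRepeat`, `protocol`.
#' @export
crossValidate <- function(type = c("HMM", "SVM"), positives, negatives,
                          repeats = 10, seed = 42, ...) {
  type <- match.arg(type)
  if (type == "HMM") {
    crossValidateHmm(positives, negatives, repeats = repeats, seed = seed, ...)
  } else {
    crossValidateSvm(positives, negatives, repeats = repeats, seed = seed, ...)
  }
}
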