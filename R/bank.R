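# Training and applying the per-subfamily model bank.

shuffleResidues <- function(seq) {
  paste(sample(strsplit(as.character(seq), "")[[1]]), collapse = "")
}

#' Negative training sequences for one subfamily
#'
#' Negatives emulate "non type II PKS domains of this subfamily": half are
#' sampled from the members of the other type II PKS classes, half are
#' residue-shuffled copies of the positives (same composition, no homology).
#' Drawn 1:1 with the positives, seeded.
#'
#' @param reference A [ReferenceSet].
#' @param key Subfamily key (e.g. `"KS_a"`).
#' @param n Number of negatives (default: the subfamily size).
#' @param seed Integer seed.
#' @return Named `AAStringSet`.
#' @export
makeNegatives <- function(reference, key, n = NULL, seed = 42) {
  d <- referenceDomains(reference)
  seqs <- referenceSequences(reference)
  kk <- splitSubfamilyKey(key)
  posIds <- d$domain_id[d$pks_class == kk$pks_class &
                        d$subfamily == kk$subfamily]
  otherIds <- d$domain_id[d$pks_class != kk$pks_class]
  if (is.null(n)) n <- length(posIds)
  withSeed(seed, {
    nOther <- min(ceiling(n / 2), length(otherIds))
    other <- sample(otherIds, nOther)
    shufSrc <- sample(posIds, n - nOther, replace = n - nOther > length(posIds))
    shuf <- vapply(as.character(seqs[shufSrc]), shuffleResidues, "")
    out <- c(stats::setNames(as.character(seqs[other]),
                             paste0("negO_", other)),
             stats::setNames(shuf, paste0("negS_", seq_along(shuf), "_",
                                          shufSrc)))
    Biostrings::AAStringSet(out)
  })
}

#' Train the per-subfamily domain classifier bank
#'
#' For every subfamily with at least `minTrain` member sequences, trains a
#' calibrated profile HMM and an RBF-SVM over alignment-score features,
#' cross-validates both, and (under the `"best_cv"` policy) selects per
#' subfamily the classifier with the higher mean product of sensitivity and
#' specificity (ties go to the HMM). Smaller subfamilies get a best-homolog
#' fallback: a query is assigned when its best local alignment against the
#' subfamily members reaches the e-value cutoff.
#'
#' @param reference A [ReferenceSet].
#' @param policy `"best_cv"` (default), `"union"` or `"intersection"` —
#'   how the two classifier types are combined at query time.
#' @param seed Integer seed for all stochastic steps.
#' @param minTrain Minimum subfamily size for trained classifiers
#'   (default 5; smaller subfamilies use the homology fallback).
#' @param selectionRepeats Cross-validation repeats used for model and
#'   parameter selection (reported evaluation uses [evaluateClassifiers()]
#'   with the 10-repeat protocol).
#' @param grid SVM parameter grid (default [defaultSvmGrid()]).
#' @param hmmMargin Profile calibration margin in bits.
#' @param homologyEvalue E-value cutoff of the homology fallback.
#' @inheritParams alignLocal
#' @param verbose Print progress.
#' @return A [ModelBank].
#' @export
trainModelBank <- function(reference, policy = "best_cv", seed = 42,
                           minTrain = 5, selectionRepeats = 3,
                           grid = defaultSvmGrid(), hmmMargin = 10,
                           homologyEvalue = 1e-10, matrix = "BLOSUM62",
                           gapOpen = 11, gapExtend = 1, verbose = FALSE) {
  d <- referenceDomains(reference)
  seqs <- referenceSequences(reference)
  keys <- unique(subfamilyKey(d$pks_class, d$subfamily))
  models <- list()
  for (i in seq_along(keys)) {
    key <- keys[i]
    kk <- splitSubfamilyKey(key)
    ids <- d$domain_id[d$pks_class == kk$pks_class &
                       d$subfamily == kk$subfamily]
    members <- seqs[ids]
    if (length(ids) < minTrain) {
      models[[key]] <- list(method = "homology", members = ids,
                            hmm = NULL, svm = NULL)
      next
    }
    if (verbose) message("training ", key, " (n = ", length(ids), ")")
    subSeed <- seed + 131L * i
    negatives <- makeNegatives(reference, key, seed = subSeed)
    profile <- buildProfile(buildMsa(members), name = key,
                            margin = hmmMargin)
    hmmCv <- crossValidateHmm(members, negatives, margin = hmmMargin,
                              repeats = selectionRepeats, seed = subSeed)
    svmModel <- trainSvm(members, negatives, grid = grid,
                         repeats = selectionRepeats, seed = subSeed,
                         matrix = matrix, gapOpen = gapOpen,
                         gapExtend = gapExtend)
    hmmProd <- prod(hmmCv$metrics[c("SN", "SP")]) / 1e4
    svmProd <- prod(svmModel$cvMetrics[c("SN", "SP")]) / 1e4
    models[[key]] <- list(
      method = if (svmProd > hmmProd) "SVM" else "HMM",
      members = ids,
      hmm = c(profile, list(cvMetrics = hmmCv$metrics, cvProduct = hmmProd)),
      svm = svmModel)
  }
  new("ModelBank", models = models, policy = policy, reference = reference,
      params = list(seed = seed, minTrain = minTrain,
                    selectionRepeats = selectionRepeats,
                    hmmMargin = hmmMargin, homologyEvalue = homologyEvalue,
                    matrix = matrix, gapOpen = gapOpen,
                    gapExtend = gapExtend))
}

#' Compare HMM and SVM classifiers per subfamily
#'
#' The evaluation harness behind the classifier-comparison table: for each
#' trainable subfamily it cross-validates both classifier types with the
#' 10-repeat protocol and reports SN/SP/AC/MCC for each, plus which type
#' wins on the product of sensitivity and specificity.
#'
#' @param reference A [ReferenceSet].
#' @param keys Subfamily keys to evaluate (default: all with at least
#'   `minTrain` members).
#' @param repeats Cross-validation repeats (default 10).
#' @param seed Integer seed.
#' @param minTrain Minimum subfamily size to evaluate.
#' @param C,gamma SVM parameters (fixed here; use [trainSvm()] for the grid
#'   search).
#' @param hmmMargin Profile calibration margin.
#' @return `data.frame` with one row per subfamily: `n`, `protocol`,
#'   `hmm_SN` ... `svm_MCC`, `winner`.
#' @export
evaluateClassifiers <- function(reference, keys = NULL, repeats = 10,
                                seed = 42, minTrain = 5, C = 4,
                                gamma = 2^-7, hmmMargin = 10) {
  d <- referenceDomains(reference)
  seqs <- referenceSequences(reference)
  allKeys <- unique(subfamilyKey(d$pks_class, d$subfamily))
  if (is.null(keys)) {
    sz <- table(subfamilyKey(d$pks_class, d$subfamily))
    keys <- allKeys[sz[allKeys] >= minTrain]
  }
  rows <- lapply(seq_along(keys), function(i) {
    kk <- splitSubfamilyKey(keys[i])
    ids <- d$domain_id[d$pks_class == kk$pks_class &
                       d$subfamily == kk$subfamily]
    subSeed <- seed + 131L * i
    negatives <- makeNegatives(reference, keys[i], seed = subSeed)
    h <- crossValidateHmm(seqs[ids], negatives, margin = hmmMargin,
                          repeats = repeats, seed = subSeed)
    s <- crossValidateSvm(seqs[ids], negatives, C = C, gamma = gamma,
                          repeats = repeats, seed = subSeed)
    hp <- prod(h$metrics[c("SN", "SP")]); sp <- prod(s$metrics[c("SN", "SP")])
    data.frame(subfamily_key = keys[i], n = length(ids),
               protocol = h$protocol,
               hmm_SN = h$metrics["SN"], hmm_SP = h$metrics["SP"],
               hmm_AC = h$metrics["AC"], hmm_MCC = h$metrics["MCC"],
               svm_SN = s$metrics["SN"], svm_SP = s$metrics["SP"],
               svm_AC = s$metrics["AC"], svm_MCC = s$metrics["MCC"],
               winner = if (sp > hp) "SVM" else if (hp > sp) "HMM" else "tie",
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
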