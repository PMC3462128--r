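# Applying a trained model bank to query proteins.

emptyCalls <- function() {
  data.frame(gene_id = character(0), pks_class = character(0),
             subfamily = character(0), method = character(0),
             score = numeric(0), evalue = numeric(0),
             dom_start = integer(0), dom_end = integer(0),
             homolog = character(0), margin = numeric(0),
             stringsAsFactors = FALSE)
}

# Candidate calls of every subfamily model on a set of proteins; one row per
# (protein, subfamily) positive. `margin` is the distance above the model's
# decision boundary in its native scale (bits above threshold for HMM and
# homology, decision value for SVM) and is used only to rank calls.
candidateCalls <- function(seqs, bank) {
  models <- bank@models
  params <- bank@params
  refSeqs <- referenceSequences(bank@reference)
  out <- list()

  useHmm <- vapply(models, function(m) {
    !is.null(m$hmm) && (bank@policy != "best_cv" || m$method == "HMM")
  }, TRUE)
  useSvm <- vapply(models, function(m) {
    !is.null(m$svm) && (bank@policy != "best_cv" || m$method == "SVM")
  }, TRUE)

  hmmHits <- NULL
  if (any(useHmm)) {
    profiles <- lapply(models[useHmm], `[[`, "hmm")
    hmmHits <- scoreProfiles(profiles, seqs)
  }
  svmHits <- list()
  for (key in names(models)[useSvm]) {
    svmHits[[key]] <- svmClassify(models[[key]]$svm, seqs)
  }

  for (key in names(models)) {
    m <- models[[key]]
    kk <- splitSubfamilyKey(key)
    hmmPos <- NULL
    if (useHmm[[key]] && !is.null(hmmHits)) {
      h <- hmmHits[hmmHits$profile == key & hmmHits$bits >= m$hmm$threshold, ]
      if (nrow(h) > 0) {
        hmmPos <- data.frame(gene_id = h$seq_id, pks_class = kk$pks_class,
                             subfamily = kk$subfamily, method = "HMM",
                             score = h$bits, evalue = h$evalue,
                             dom_start = h$env_from, dom_end = h$env_to,
                             homolog = NA_character_,
                             margin = h$bits - m$hmm$threshold,
                             stringsAsFactors = FALSE)
      }
    }
    svmPos <- NULL
    if (useSvm[[key]]) {
      s <- svmHits[[key]]
      s <- s[s$positive, , drop = FALSE]
      if (nrow(s) > 0) {
        # the SVM is sequence-global: its implied span is the whole protein
        svmPos <- data.frame(gene_id = s$seq_id, pks_class = kk$pks_class,
                             subfamily = kk$subfamily, method = "SVM",
                             score = s$decision, evalue = NA_real_,
                             dom_start = 1L,
                             dom_end = Biostrings::width(seqs)[
                               match(s$seq_id, names(seqs))],
                             homolog = NA_character_, margin = s$decision,
                             stringsAsFactors = FALSE)
      }
    }
    if (bank@policy == "intersection" && !is.null(m$hmm) && !is.null(m$svm)) {
      if (!is.null(hmmPos)) {
        keep <- hmmPos$gene_id %in% (svmPos$gene_id %||% character(0))
        hmmPos <- hmmPos[keep, , drop = FALSE]
      }
      svmPos <- NULL # report the HMM call (it carries an envelope)
    } else if (bank@policy == "union" && !is.null(svmPos) &&
               !is.null(hmmPos)) {
      svmPos <- svmPos[!svmPos$gene_id %in% hmmPos$gene_id, , drop = FALSE]
    }
    out[[length(out) + 1L]] <- hmmPos
    out[[length(out) + 1L]] <- svmPos

    if (m$method == "homology") {
      members <- refSeqs[m$members]
      rows <- lapply(names(seqs), function(id) {
        q <- as.character(seqs[[id]])
        sc <- localScores(q, members, matrix = params$matrix,
                          gapOpen = params$gapOpen,
                          gapExtend = params$gapExtend)
        best <- which.max(sc)
        ev <- alignmentEvalue(sc[best], nchar(q),
                              Biostrings::width(members)[best])
        if (ev > params$homologyEvalue) return(NULL)
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(maskAmbiguous(q)),
          Biostrings::AAString(maskAmbiguous(
            as.character(members[[best]]))),
          type = "local",
          substitutionMatrix = substitutionMatrix(params$matrix),
          gapOpening = params$gapOpen, gapExtension = params$gapExtend)
        data.frame(gene_id = id, pks_class = kk$pks_class,
                   subfamily = kk$subfamily, method = "homology",
                   score = sc[best], evalue = ev,
                   dom_start = BiocGenerics::start(pattern(aln)),
                   dom_end = BiocGenerics::end(pattern(aln)),
                   homolog = names(members)[best],
                   margin = log10(params$homologyEvalue) - log10(ev),
                   stringsAsFactors = FALSE)
      })
      out[[length(out) + 1L]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) return(emptyCalls())
  rownames(res) <- NULL
  res
}

#' Classify proteins into type II PKS domain subfamilies
#'
#' Evaluates every subfamily model of the bank on each protein and retains
#' at most two calls per protein (type II PKS proteins carry at most two
#' domains), keeping higher-ranked calls first and dropping any call whose
#' implied domain span overlaps an already-kept call by more than
#' `maxOverlap` of the shorter span.
#'
#' @param seqs Named `AAStringSet` (or character vector) of proteins.
#' @param bank A [ModelBank].
#' @param maxCalls Maximum calls per protein (default 2).
#' @param maxOverlap Maximum tolerated span overlap, as a fraction of the
#'   shorter span (default 0.2).
#' @return `data.frame` of domain calls: `gene_id`, `pks_class`,
#'   `subfamily`, `method`, `score`, `evalue`, `dom_start`, `dom_end`,
#'   `homolog`. Proteins with no call are absent.
#' @export
classifyProteins <- function(seqs, bank, maxCalls = 2, maxOverlap = 0.2) {
  seqs <- Biostrings::AAStringSet(seqs)
  if (length(seqs) == 0) return(emptyCalls())
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  cand <- candidateCalls(seqs, bank)
  if (nrow(cand) == 0) return(emptyCalls())
  kept <- list()
  for (id in unique(cand$gene_id)) {
    cc <- cand[cand$gene_id == id, , drop = FALSE]
    cc <- cc[order(-cc$margin, cc$pks_class, cc$subfamily), , drop = FALSE]
    sel <- integer(0)
    for (i in seq_len(nrow(cc))) {
      if (length(sel) >= maxCalls) break
      ok <- all(vapply(sel, function(j) {
        ov <- min(cc$dom_end[i], cc$dom_end[j]) -
          max(cc$dom_start[i], cc$dom_start[j]) + 1
        shorter <- min(cc$dom_end[i] - cc$dom_start[i],
                       cc$dom_end[j] - cc$dom_start[j]) + 1
        ov <= maxOverlap * shorter
      }, TRUE))
      if (ok) sel <- c(sel, i)
    }
    kept[[id]] <- cc[sel, , drop = FALSE]
  }
  res <- do.call(rbind, kept)
  res <- res[order(match(res$gene_id, names(seqs)), -res$margin), ]
  rownames(res) <- NULL
  res[, setdiff(names(res), "margin")]
}

#' Classify a single protein
#'
#' @param seq One amino-acid sequence.
#' @param bank A [ModelBank].
#' @param ... Passed to [classifyProteins()].
#' @return `data.frame` of at most two domain calls (zero rows if none).
#' @export
classifyProtein <- function(seq, bank, ...) {
  classifyProteins(Biostrings::AAStringSet(c(query = as.character(seq))),
                   bank, ...)
}
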