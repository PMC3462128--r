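# Aromatic polyketide chemotype prediction from ARO/CYC subfamily
# combinations, with a homolog-majority fallback for the combinations
# shared by two chemotypes.

normalizeCombination <- function(x) sort(unique(x))

# A combination is unique iff no other chemotype has an identical one.
recomputeUniqueness <- function(combinations, chemotypes = NULL) {
  keys <- vapply(lapply(combinations, normalizeCombination),
                 paste, "", collapse = ",")
  if (is.null(chemotypes)) chemotypes <- seq_along(combinations)
  vapply(seq_along(keys), function(i) {
    !any(keys == keys[i] & chemotypes != chemotypes[i])
  }, TRUE)
}

#' Load the chemotype rule table
#'
#' Reads the embedded table of ARO/CYC subfamily combinations observed per
#' aromatic polyketide chemotype (11 rules over 6 chemotypes), recomputes
#' the uniqueness flags from the combinations and asserts they equal the
#' shipped flags.
#'
#' @param path Path to a rule TSV (default: the table shipped with the
#'   package). Columns: `chemotype`, `chemotype_name`, `combination`
#'   (comma-separated subfamily keys), `unique` (`yes`/`no`).
#' @return A [RuleTable].
#' @examples
#' rt <- loadRuleTable()
#' countUnique(rt)
#' @export
loadRuleTable <- function(path = system.file("extdata",
                                             "chemotype_rules.tsv",
                                             package = "t2pks")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  combos <- lapply(strsplit(raw$combination, ",", fixed = TRUE),
                   normalizeCombination)
  rules <- data.frame(chemotype = raw$chemotype,
                      chemotype_name = raw$chemotype_name,
                      stringsAsFactors = FALSE)
  rules$combination <- I(combos)
  rules$unique <- recomputeUniqueness(combos, raw$chemotype)
  if (!identical(rules$unique, raw$unique == "yes")) {
    stop("rule table corrupt: recomputed uniqueness flags disagree ",
         "with the shipped flags")
  }
  new("RuleTable", rules = rules)
}

#' Number of unique domain combinations in a rule table
#'
#' @param rt A [RuleTable].
#' @return Integer: rules whose combination occurs under exactly one
#'   chemotype.
#' @export
countUnique <- function(rt) {
  stopifnot(is(rt, "RuleTable"))
  sum(ruleRows(rt)$unique)
}

#' Chemotype pairs sharing an identical domain combination
#'
#' @param rt A [RuleTable].
#' @return `data.frame` with columns `chemotype1`, `chemotype2` (unordered,
#'   deduplicated, sorted) and `combination` (the shared key string).
#' @export
overlappingPairs <- function(rt) {
  r <- ruleRows(rt)
  keys <- vapply(r$combination, paste, "", collapse = ",")
  out <- list()
  if (nrow(r) >= 2) {
    idx <- utils::combn(nrow(r), 2)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      if (keys[i] == keys[j] && r$chemotype[i] != r$chemotype[j]) {
        pair <- sort(c(r$chemotype[i], r$chemotype[j]))
        out[[length(out) + 1L]] <- data.frame(
          chemotype1 = pair[1], chemotype2 = pair[2],
          combination = keys[i], stringsAsFactors = FALSE)
      }
    }
  }
  res <- unique(do.call(rbind, out) %||%
                  data.frame(chemotype1 = character(0),
                             chemotype2 = character(0),
                             combination = character(0)))
  rownames(res) <- NULL
  res[order(res$chemotype1, res$chemotype2), , drop = FALSE]
}

#' ARO/CYC subfamily signature of a cluster
#'
#' The set of distinct aromatase/cyclase subfamily keys among a cluster's
#' domain calls; all other classes are ignored. This is the quantity the
#' rule table is matched against.
#'
#' @param x A [PksCluster] or a domain-call `data.frame` with columns
#'   `pks_class` and `subfamily`.
#' @return Sorted character vector of subfamily keys (possibly empty).
#' @export
clusterSignature <- function(x) {
  calls <- if (is(x, "PksCluster")) domainCalls(x) else x
  keep <- calls$pks_class %in% c("ARO", "CYC")
  normalizeCombination(subfamilyKey(calls$pks_class[keep],
                                    calls$subfamily[keep]))
}

#' Homolog-majority chemotype vote for a cluster
#'
#' For each ARO/CYC domain call in the cluster, collects reference ARO/CYC
#' domains whose local-alignment e-value against the calling gene's protein
#' is at or below the cutoff (every such homolog contributes, not just the
#' best hit) and tallies the chemotypes of their source clusters. Ties are
#' reported as ambiguous with all tied chemotypes listed.
#'
#' @param cluster A [PksCluster].
#' @param reference A [ReferenceSet] whose ARO/CYC domains carry chemotype
#'   labels.
#' @param evalueCutoff Homolog e-value cutoff (default 1e-10).
#' @inheritParams alignLocal
#' @return List with `tally` (named counts, decreasing), `winners`
#'   (chemotype code(s) with the top count; length > 1 on a tie) and
#'   `ambiguous`.
#' @export
homologVote <- function(cluster, reference, evalueCutoff = 1e-10,
                        matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1) {
  d <- referenceDomains(reference)
  seqs <- referenceSequences(reference)
  refIdx <- d$pks_class %in% c("ARO", "CYC") & !is.na(d$chemotype)
  refSeqs <- seqs[d$domain_id[refIdx]]
  refChem <- d$chemotype[refIdx]
  calls <- domainCalls(cluster)
  calls <- calls[calls$pks_class %in% c("ARO", "CYC"), , drop = FALSE]
  votes <- character(0)
  for (i in seq_len(nrow(calls))) {
    q <- as.character(cluster@proteins[[calls$gene_id[i]]])
    if (length(refSeqs) == 0) next
    sc <- localScores(q, refSeqs, matrix = matrix, gapOpen = gapOpen,
                      gapExtend = gapExtend)
    ev <- alignmentEvalue(sc, nchar(q), Biostrings::width(refSeqs))
    votes <- c(votes, refChem[ev <= evalueCutoff])
  }
  if (length(votes) == 0) {
    return(list(tally = integer(0), winners = character(0),
                ambiguous = FALSE))
  }
  tally <- sort(table(votes), decreasing = TRUE)
  tally <- stats::setNames(as.integer(tally), names(tally))
  winners <- sort(names(tally)[tally == max(tally)])
  list(tally = tally, winners = winners, ambiguous = length(winners) > 1)
}

#' Predict the aromatic polyketide chemotype of a valid cluster
#'
#' Two-rule procedure: (1) if the cluster's ARO/CYC signature equals a
#' combination unique to one chemotype, that chemotype is assigned;
#' (2) if it equals a combination shared by two chemotypes, the most
#' abundant chemotype among reference homologs of the cluster's ARO/CYC
#' domains is assigned. Any other signature — including the empty one of a
#' minimal KS+CLF cluster — leaves the chemotype unclassified. Matching is
#' exact set equality by default; with `relaxed = TRUE` a signature matches
#' any rule whose combination it contains, the largest matching combination
#' winning (ties among equally specific rules fall through to the vote).
#'
#' @param cluster A valid [PksCluster] (KS and CLF present); invalid
#'   clusters are an error — filter them first.
#' @param rt A [RuleTable].
#' @param reference A [ReferenceSet] for the homolog vote.
#' @param evalueCutoff Homolog e-value cutoff (default 1e-10).
#' @param relaxed Use subset matching instead of exact set equality.
#' @inheritParams alignLocal
#' @return A [ChemotypePrediction].
#' @export
predictChemotype <- function(cluster, rt, reference, evalueCutoff = 1e-10,
                             relaxed = FALSE, matrix = "BLOSUM62",
                             gapOpen = 11, gapExtend = 1) {
  stopifnot(is(cluster, "PksCluster"), is(rt, "RuleTable"))
  if (!clusterValid(cluster)) {
    stop("chemotype prediction requires a valid (KS+CLF) cluster")
  }
  sig <- clusterSignature(cluster)
  r <- ruleRows(rt)
  keys <- vapply(r$combination, paste, "", collapse = ",")
  sigKey <- paste(sig, collapse = ",")
  unclassified <- function() {
    new("ChemotypePrediction", chemotype = UNCLASSIFIED,
        rulePath = "unclassified", signature = sig,
        votes = data.frame(chemotype = character(0), n = integer(0)),
        ambiguous = FALSE)
  }
  hit <- which(keys == sigKey)
  if (length(hit) == 0 && relaxed) {
    sup <- which(vapply(r$combination,
                        function(cc) all(cc %in% sig), TRUE))
    if (length(sup) > 0) {
      sizes <- lengths(r$combination[sup])
      hit <- sup[sizes == max(sizes)]
      if (length(unique(r$chemotype[hit])) == 1 && !all(r$unique[hit])) {
        hit <- hit # single chemotype via an overlapped row: vote below
      }
    }
  }
  if (length(hit) == 0) return(unclassified())
  if (length(unique(r$chemotype[hit])) == 1 && all(r$unique[hit])) {
    return(new("ChemotypePrediction", chemotype = r$chemotype[hit[1]],
               rulePath = "unique_match", signature = sig,
               votes = data.frame(chemotype = character(0), n = integer(0)),
               ambiguous = FALSE))
  }
  vote <- homologVote(cluster, reference, evalueCutoff = evalueCutoff,
                      matrix = matrix, gapOpen = gapOpen,
                      gapExtend = gapExtend)
  if (length(vote$winners) == 0) return(unclassified())
  new("ChemotypePrediction",
      chemotype = paste(vote$winners, collapse = "|"),
      rulePath = "homolog_vote", signature = sig,
      votes = data.frame(chemotype = names(vote$tally),
                         n = unname(vote$tally), stringsAsFactors = FALSE),
      ambiguous = vote$ambiguous)
}
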