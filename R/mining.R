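# Genome scanning, cluster chaining by genomic distance, cluster validation
# and novel-annotation flagging.

# Product keywords naming the known type II PKS classes; a gene whose prior
# annotation matches none of these but receives a domain call is "novel".
PKS_PRODUCT_KEYWORDS <- c(
  "keto synthase", "ketosynthase", "beta-ketoacyl", "ketoacyl synthase",
  "chain length factor", "acyl carrier", "keto reductase", "ketoreductase",
  "aromatase", "cyclase", "acyl-coa ligase", "acyl coa ligase",
  "acyl transferase", "acyltransferase", "malonyl", "thioesterase")

#' Scan a genome's proteins for type II PKS domains
#'
#' Applies the domain classifiers to every gene and returns the calls of
#' genes with at least one call, joined with genomic coordinates.
#'
#' @param genome A [GenomeRecord].
#' @param bank A [ModelBank].
#' @param ... Passed to [classifyProteins()].
#' @return `data.frame` of positioned domain calls (columns of
#'   [classifyProteins()] plus `start`, `end`, `strand`, `locus_tag`,
#'   `product`).
#' @export
scanGenome <- function(genome, bank, ...) {
  g <- genomeGenes(genome)
  prot <- genomeProteins(genome)
  base <- data.frame(gene_id = S4Vectors::mcols(g)$gene_id,
                     start = BiocGenerics::start(g),
                     end = BiocGenerics::end(g),
                     strand = as.character(BiocGenerics::strand(g)),
                     locus_tag = S4Vectors::mcols(g)$locus_tag,
                     product = S4Vectors::mcols(g)$product,
                     stringsAsFactors = FALSE)
  if (length(prot) == 0) {
    return(cbind(emptyCalls(), base[0, -1, drop = FALSE]))
  }
  calls <- classifyProteins(prot, bank, ...)
  merged <- merge(calls, base, by = "gene_id", sort = FALSE)
  merged[order(merged$start, merged$gene_id), , drop = FALSE]
}

# Connected components of genes under the "gap < maxGap" relation. The gap
# between two genes is the number of intervening base pairs between their
# bodies: next.start - prev.end - 1. Strand is ignored.
chainGeneIds <- function(starts, ends, ids, maxGap) {
  ord <- order(starts, ends, ids)
  starts <- starts[ord]; ends <- ends[ord]; ids <- ids[ord]
  groups <- list(); cur <- 1L; reach <- ends[1]
  grp <- integer(length(ids)); grp[1] <- 1L
  for (i in seq_along(ids)[-1]) {
    gap <- starts[i] - reach - 1
    if (gap < maxGap) {
      grp[i] <- cur
    } else {
      cur <- cur + 1L
      grp[i] <- cur
    }
    reach <- max(reach, ends[i])
  }
  split(ids, grp)
}

#' Chain positioned domain calls into candidate gene clusters
#'
#' Single-linkage chaining along the genome: two called genes belong to the
#' same cluster iff they are connected by a chain of neighbor pairs, each
#' with strictly fewer than `maxGap` intervening base pairs between the
#' gene bodies (`next.start - prev.end - 1 < maxGap`). Genes with two
#' domain calls contribute both. Singleton clusters are kept (they fail
#' validation later unless they carry both KS and CLF).
#'
#' @param genome The [GenomeRecord] the calls came from.
#' @param calls Positioned calls from [scanGenome()].
#' @param maxGap Chaining distance in bp (default 15000, strict).
#' @return List of [PksCluster] ordered by genomic start, ids
#'   `cluster_1`, `cluster_2`, ...; validity flags already set.
#' @export
chainClusters <- function(genome, calls, maxGap = 15000) {
  if (nrow(calls) == 0) return(list())
  genes <- unique(calls[, c("gene_id", "start", "end")])
  groups <- chainGeneIds(genes$start, genes$end, genes$gene_id, maxGap)
  groups <- groups[order(vapply(groups, function(ids) {
    min(genes$start[genes$gene_id %in% ids])
  }, 0))]
  g <- genomeGenes(genome)
  prot <- genomeProteins(genome)
  clusters <- lapply(seq_along(groups), function(i) {
    ids <- groups[[i]]
    sel <- which(S4Vectors::mcols(g)$gene_id %in% ids)
    sel <- sel[order(BiocGenerics::start(g)[sel])]
    cc <- calls[calls$gene_id %in% ids, , drop = FALSE]
    new("PksCluster", clusterId = paste0("cluster_", i),
        accession = genomeAccession(genome), genes = g[sel],
        proteins = prot[S4Vectors::mcols(g)$gene_id[sel]],
        calls = cc, valid = NA,
        chemotype = new("ChemotypePrediction", chemotype = UNCLASSIFIED,
                        rulePath = "unclassified", signature = character(0),
                        votes = data.frame(chemotype = character(0),
                                           n = integer(0)),
                        ambiguous = FALSE),
        syntheticCoords = genome@syntheticCoords)
  })
  validateClusters(clusters)
}

#' Validate candidate clusters by the KS+CLF criterion
#'
#' A cluster is a valid type II PKS gene cluster iff it contains at least
#' one ketosynthase (KS) call and at least one chain length factor (CLF)
#' call — the heterodimeric condensing pair without which no polyketide can
#' be made. Invalid clusters are retained (flagged) but excluded from
#' chemotype prediction and headline counts.
#'
#' @param clusters List of [PksCluster].
#' @return The list with `valid` flags set.
#' @export
validateClusters <- function(clusters) {
  lapply(clusters, function(cl) {
    cls <- domainCalls(cl)$pks_class
    cl@valid <- ("KS" %in% cls) && ("CLF" %in% cls)
    cl
  })
}

#' Flag genes newly annotated as type II PKS
#'
#' Genes that received a domain call but whose prior product annotation
#' names none of the type II PKS classes (case-insensitive keyword match)
#' are reported as newly annotated; missing products count as "unknown".
#'
#' @param genome A [GenomeRecord].
#' @param calls Positioned calls from [scanGenome()].
#' @return `data.frame` with columns `gene_id`, `prior_product`,
#'   `pks_class`, `subfamily`.
#' @export
flagNovelAnnotations <- function(genome, calls) {
  empty <- data.frame(gene_id = character(0), prior_product = character(0),
                      pks_class = character(0), subfamily = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  first <- calls[!duplicated(calls$gene_id), , drop = FALSE]
  prior <- first$product
  prior[is.na(prior) | !nzchar(prior)] <- "unknown"
  known <- vapply(tolower(prior), function(p) {
    any(vapply(PKS_PRODUCT_KEYWORDS, grepl, TRUE, x = p, fixed = TRUE))
  }, TRUE)
  out <- data.frame(gene_id = first$gene_id, prior_product = prior,
                    pks_class = first$pks_class,
                    subfamily = first$subfamily,
                    stringsAsFactors = FALSE)[!known, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine a genome end to end
#'
#' Scans all proteins with the model bank, chains the called genes into
#' clusters (< `maxGap` intervening bp), validates clusters by the KS+CLF
#' criterion, predicts the aromatic polyketide chemotype of each valid
#' cluster and flags newly annotated genes.
#'
#' @param genome A [GenomeRecord].
#' @param bank A [ModelBank].
#' @param ruleTable A [RuleTable] (default: the shipped table).
#' @param maxGap Chaining distance in bp (default 15000).
#' @param evalueCutoff Homolog-vote e-value cutoff.
#' @param relaxed Relaxed (subset) rule matching; see [predictChemotype()].
#' @return A [MiningResult].
#' @export
mineGenome <- function(genome, bank, ruleTable = loadRuleTable(),
                       maxGap = 15000, evalueCutoff = 1e-10,
                       relaxed = FALSE) {
  calls <- scanGenome(genome, bank)
  clusters <- chainClusters(genome, calls, maxGap = maxGap)
  clusters <- lapply(clusters, function(cl) {
    if (clusterValid(cl)) {
      cl@chemotype <- predictChemotype(cl, ruleTable, bank@reference,
                                       evalueCutoff = evalueCutoff,
                                       relaxed = relaxed,
                                       matrix = bank@params$matrix,
                                       gapOpen = bank@params$gapOpen,
                                       gapExtend = bank@params$gapExtend)
    }
    cl
  })
  new("MiningResult", accession = genomeAccession(genome),
      organism = genome@organism, lengthBp = genome@lengthBp,
      clusters = clusters, calls = calls,
      nPksProteins = length(unique(calls$gene_id)),
      novel = flagNovelAnnotations(genome, calls),
      syntheticCoords = genome@syntheticCoords)
}
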