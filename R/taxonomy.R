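# Survey-level summaries: per-taxon group ratios and per-genome cluster
# tables.

#' @importFrom stats aggregate
NULL

#' Taxonomic PKS group ratio from count pairs
#'
#' The percentage of sequenced genomes in a taxon that contain at least one
#' valid type II PKS gene cluster, rounded half-up to two decimals.
#'
#' @param nSequenced,nWithPks Integer vectors (element-wise).
#' @return Numeric vector of percentages (2 decimals).
#' @examples
#' groupRatioFromCounts(11, 6)  # 54.55
#' groupRatioFromCounts(7, 5)   # 71.43
#' @export
groupRatioFromCounts <- function(nSequenced, nWithPks) {
  stopifnot(all(nSequenced >= 1), all(nWithPks >= 0),
            all(nWithPks <= nSequenced))
  roundHalfUp(100 * nWithPks / nSequenced, 2)
}

#' Per-taxon summary of mining results
#'
#' Buckets genomes by a taxonomic rank of their lineage (default suborder),
#' counts genomes with at least one valid cluster, and computes the group
#' ratio per bucket. Genomes lacking the rank are bucketed as
#' `"unranked"`.
#'
#' @param genomes List of [GenomeRecord].
#' @param results Parallel list of [MiningResult].
#' @param rank Lineage rank to bucket by (default `"suborder"`).
#' @return `data.frame` with columns `order`, `suborder` (or the chosen
#'   rank), `n_sequenced`, `n_with_pks`, `group_ratio`, sorted by order
#'   then rank value.
#' @export
taxonGroupRatio <- function(genomes, results, rank = "suborder") {
  stopifnot(length(genomes) == length(results))
  rows <- lapply(seq_along(genomes), function(i) {
    lin <- genomes[[i]]@lineage
    getRank <- function(r) {
      v <- lin$name[lin$rank == r]
      if (length(v) == 0) "unranked" else v[1]
    }
    hasPks <- any(vapply(pksClusters(results[[i]]), clusterValid, TRUE))
    data.frame(order = getRank("order"), value = getRank(rank),
               has_pks = hasPks, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  agg <- aggregate(cbind(n_sequenced = rep(1, nrow(rows)),
                         n_with_pks = as.integer(rows$has_pks)) ~
                     order + value, data = rows, FUN = sum)
  agg$group_ratio <- groupRatioFromCounts(agg$n_sequenced, agg$n_with_pks)
  names(agg)[names(agg) == "value"] <- rank
  agg <- agg[order(agg$order, agg[[rank]]), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Published survey census of actinobacterial suborders
#'
#' The per-suborder counts of the 319-genome actinobacterial survey
#' (sequenced genomes and genomes with at least one valid type II PKS
#' cluster), shipped as package data, with group ratios recomputed from
#' the counts.
#'
#' @return `data.frame` with columns `order`, `suborder`, `n_sequenced`,
#'   `n_with_pks`, `group_ratio`.
#' @export
surveyTaxonCounts <- function() {
  path <- system.file("extdata", "actinobacteria_survey_taxa.tsv",
                      package = "t2pks")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$group_ratio <- groupRatioFromCounts(tab$n_sequenced, tab$n_with_pks)
  tab
}

#' Per-genome summary rows of mining results
#'
#' One row per genome with at least one valid cluster: organism, genome
#' size, the number of type II PKS proteins in valid clusters, and the
#' tally of predicted chemotypes over valid clusters (including
#' unclassified). Ambiguous homolog-vote ties are counted as unclassified
#' here, since a summary row must commit to one column per cluster.
#'
#' @param results List of [MiningResult] (or a single one).
#' @return `data.frame` with columns `organism`, `accession`, `size_bp`,
#'   `n_type2_pks`, then one count column per chemotype code
#'   (`Unc`, `Ang`, `Ant`, `Ben`, `Pen`, `Tcm`, `Tet/Aur`).
#' @export
genomeSummary <- function(results) {
  if (is(results, "MiningResult")) results <- list(results)
  codes <- c(UNCLASSIFIED, names(CHEMOTYPE_CODES))
  rows <- lapply(results, function(res) {
    valid <- Filter(clusterValid, pksClusters(res))
    if (length(valid) == 0) return(NULL)
    chem <- vapply(valid, function(cl) cl@chemotype@chemotype, "")
    chem[!chem %in% codes] <- UNCLASSIFIED
    tally <- table(factor(chem, levels = codes))
    genesInValid <- unique(unlist(lapply(valid, function(cl) {
      unique(domainCalls(cl)$gene_id)
    })))
    cbind(data.frame(organism = res@organism, accession = res@accession,
                     size_bp = res@lengthBp,
                     n_type2_pks = length(genesInValid),
                     stringsAsFactors = FALSE),
          as.data.frame(rbind(as.integer(tally))) |>
            stats::setNames(codes))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    out <- data.frame(organism = character(0), accession = character(0),
                      size_bp = numeric(0), n_type2_pks = integer(0))
    for (cd in codes) out[[cd]] <- integer(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
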