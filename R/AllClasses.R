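#' @import methods
#' @importClassesFrom Biostrings AAStringSet
NULL

#' ReferenceSet: a labeled set of type II PKS domain sequences
#'
#' Container for the curated reference set the whole pipeline is anchored to:
#' one amino-acid sequence per domain, each carrying its type II PKS class
#' (KS, CLF, ACP, KR, ARO, CYC, KSIII, AL, AT, MCAT, TE), subfamily letter,
#' source gene cluster and, where known, the aromatic polyketide chemotype of
#' that cluster. Didomain proteins (the N-/C-terminal halves of didomain
#' aromatases) contribute two domain rows sharing one `gene_name`.
#'
#' @slot sequences [Biostrings::AAStringSet] named by `domain_id`.
#' @slot domains `data.frame` with columns `domain_id`, `gene_name`,
#'   `pks_class`, `subfamily`, `source_cluster`, `chemotype` (NA when the
#'   source cluster's product class is unknown or not applicable).
#' @seealso [loadReferenceSet()], [generateReferenceSet()]
#' @export
setClass("ReferenceSet",
  representation(sequences = "AAStringSet", domains = "data.frame"))

setValidity("ReferenceSet", function(object) {
  d <- object@domains
  need <- c("domain_id", "gene_name", "pks_class", "subfamily",
            "source_cluster", "chemotype")
  if (!all(need %in% names(d))) {
    return(paste("domains must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(d$domain_id)) return("domain_id values must be unique")
  if (length(object@sequences) != nrow(d)) {
    return("one sequence per domain row required")
  }
  if (!identical(names(object@sequences), d$domain_id)) {
    return("sequence names must equal domains$domain_id, in order")
  }
  if (!all(d$pks_class %in% PKS_CLASSES)) {
    bad <- unique(d$pks_class[!d$pks_class %in% PKS_CLASSES])
    return(paste("unknown type II PKS class:", paste(bad, collapse = ", ")))
  }
  TRUE
})

#' GenomeRecord: a genome's protein-coding genes with coordinates
#'
#' A genome as the miner sees it: an accession, the organism name and
#' taxonomic lineage, gene coordinates as a [GenomicRanges::GRanges] (1-based,
#' inclusive, GenBank convention) and the corresponding protein translations.
#' When the input was a plain protein FASTA without coordinates, synthetic
#' coordinates are assigned in input order and `syntheticCoords` is `TRUE`.
#'
#' @slot accession Genome accession string.
#' @slot organism Organism name ("" when unknown).
#' @slot lineage `data.frame` with columns `rank`, `name` (may be empty).
#' @slot genes `GRanges` with metadata columns `gene_id`, `locus_tag`,
#'   `product`.
#' @slot proteins `AAStringSet` named by `gene_id`, parallel to `genes`.
#' @slot lengthBp Genome length in bp.
#' @slot syntheticCoords `TRUE` when coordinates were assigned, not parsed.
#' @seealso [readGenBank()], [readProteinFasta()], [plantGenome()]
#' @export
setClass("GenomeRecord",
  representation(accession = "character", organism = "character",
                 lineage = "data.frame", genes = "GRanges",
                 proteins = "AAStringSet", lengthBp = "numeric",
                 syntheticCoords = "logical"))

setValidity("GenomeRecord", function(object) {
  g <- object@genes
  if (length(g) != length(object@proteins)) {
    return("one protein per gene required")
  }
  if (length(g) > 0) {
    if (!all(c("gene_id", "locus_tag", "product") %in%
             names(S4Vectors::mcols(g)))) {
      return("genes need mcols gene_id, locus_tag, product")
    }
    if (!identical(names(object@proteins), S4Vectors::mcols(g)$gene_id)) {
      return("protein names must equal gene_id, in order")
    }
    if (any(BiocGenerics::end(g) > object@lengthBp)) {
      return("gene coordinates exceed genome length")
    }
    if (any(BiocGenerics::start(g) < 1)) return("gene start < 1")
  }
  TRUE
})

#' SubfamilyTable: the partition of a reference set into subfamilies
#'
#' Result of single-linkage homology clustering of each type II PKS class,
#' with the identity/coverage thresholds that produced it. One row per
#' (class, subfamily) pair; subfamily letters are assigned `a`, `b`, ... by
#' descending cluster size (ties broken by the lexicographically smallest
#' member id).
#'
#' @slot table `data.frame` with columns `pks_class`, `subfamily`,
#'   `n_members`, `mean_length` and list-column `member_ids`.
#' @slot minIdentity Percent-identity threshold used (0–100).
#' @slot minCoverage Coverage threshold used (0–1).
#' @seealso [clusterReference()], [calibrateThresholds()]
#' @export
setClass("SubfamilyTable",
  representation(table = "data.frame", minIdentity = "numeric",
                 minCoverage = "numeric"))

setValidity("SubfamilyTable", function(object) {
  t <- object@table
  need <- c("pks_class", "subfamily", "n_members", "mean_length", "member_ids")
  if (!all(need %in% names(t))) {
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(t) > 0 && !identical(t$n_members, lengths(t$member_ids))) {
    return("n_members must equal the number of member ids")
  }
  TRUE
})

#' ModelBank: trained per-subfamily domain classifiers
#'
#' Holds, for every subfamily with enough training sequences, a profile HMM
#' and an RBF-kernel SVM over Smith-Waterman score features, together with
#' their cross-validation metrics and the per-subfamily method chosen by the
#' bank policy. Subfamilies too small to train (fewer than `minTrain`
#' members) carry a homology-search fallback instead.
#'
#' @slot models Named list keyed by subfamily key (`"KS_a"`); each element a
#'   list with components `hmm`, `svm` (either may be `NULL`), `method`
#'   (`"HMM"`, `"SVM"` or `"homology"`) and `members` (training domain ids).
#' @slot policy `"best_cv"`, `"union"` or `"intersection"`.
#' @slot reference The [ReferenceSet] the bank was trained on (needed for
#'   SVM feature references, homology fallback and homolog voting).
#' @slot params List of training parameters (seed, grid, margins, cutoffs).
#' @seealso [trainModelBank()], [classifyProteins()]
#' @export
setClass("ModelBank",
  representation(models = "list", policy = "character",
                 reference = "ReferenceSet", params = "list"))

setValidity("ModelBank", function(object) {
  if (!object@policy %in% c("best_cv", "union", "intersection")) {
    return("policy must be best_cv, union or intersection")
  }
  ok <- vapply(object@models, function(m) {
    is.list(m) && m$method %in% c("HMM", "SVM", "homology")
  }, TRUE)
  if (!all(ok)) return("each model needs a method of HMM, SVM or homology")
  TRUE
})

#' ChemotypePrediction: the predicted product class of a gene cluster
#'
#' @slot chemotype Chemotype code (`"Ang"`, `"Ant"`, `"Ben"`, `"Pen"`,
#'   `"Tcm"`, `"Tet/Aur"`) or `"Unc"` for unclassified; ties in the homolog
#'   vote give the tied codes joined by `"|"` with `ambiguous = TRUE`.
#' @slot rulePath `"unique_match"`, `"homolog_vote"` or `"unclassified"`.
#' @slot signature The cluster's observed set of ARO/CYC subfamily keys.
#' @slot votes `data.frame` of homolog chemotype counts (empty unless the
#'   vote path was taken).
#' @slot ambiguous `TRUE` when the homolog vote tied.
#' @export
setClass("ChemotypePrediction",
  representation(chemotype = "character", rulePath = "character",
                 signature = "character", votes = "data.frame",
                 ambiguous = "logical"))

setValidity("ChemotypePrediction", function(object) {
  if (!object@rulePath %in% c("unique_match", "homolog_vote", "unclassified")) {
    return("rulePath must be unique_match, homolog_vote or unclassified")
  }
  if ((object@rulePath == "unclassified") != (object@chemotype == UNCLASSIFIED)) {
    return("rulePath is 'unclassified' exactly when chemotype is 'Unc'")
  }
  TRUE
})

#' PksCluster: a chained group of type II PKS genes
#'
#' @slot clusterId Identifier within the genome (e.g. `"cluster_1"`).
#' @slot accession Genome accession.
#' @slot genes `GRanges` of the member genes, sorted by start.
#' @slot proteins `AAStringSet` of member translations, named by gene id.
#' @slot calls `data.frame` of domain calls on the member genes.
#' @slot valid `TRUE` iff the cluster carries at least one KS call and one
#'   CLF call (the minimal condensing pair of a functional type II PKS).
#' @slot chemotype A [ChemotypePrediction] (unclassified until predicted).
#' @slot syntheticCoords Inherited from the genome record.
#' @export
setClass("PksCluster",
  representation(clusterId = "character", accession = "character",
                 genes = "GRanges", proteins = "AAStringSet",
                 calls = "data.frame", valid = "logical",
                 chemotype = "ChemotypePrediction",
                 syntheticCoords = "logical"))

#' MiningResult: all clusters and calls found in one genome
#'
#' @slot accession,organism,lengthBp Genome metadata carried through for
#'   reporting.
#' @slot clusters List of [PksCluster].
#' @slot calls `data.frame` of all domain calls with genomic coordinates.
#' @slot nPksProteins Number of distinct genes carrying at least one domain
#'   call across clusters.
#' @slot novel `data.frame` of newly annotated genes (prior product did not
#'   name a type II PKS class).
#' @slot syntheticCoords `TRUE` when the genome had synthetic coordinates.
#' @seealso [mineGenome()], [writeMiningReport()]
#' @export
setClass("MiningResult",
  representation(accession = "character", organism = "character",
                 lengthBp = "numeric", clusters = "list",
                 calls = "data.frame", nPksProteins = "integer",
                 novel = "data.frame", syntheticCoords = "logical"))

#' RuleTable: ARO/CYC domain-combination rules for chemotype prediction
#'
#' The printed table of aromatase/cyclase subfamily combinations observed in
#' known aromatic polyketide gene clusters, one row per (chemotype,
#' combination) pair, with a uniqueness flag: a combination is unique when no
#' other chemotype shares it.
#'
#' @slot rules `data.frame` with columns `chemotype` (code), `chemotype_name`,
#'   list-column `combination` (sorted subfamily keys) and `unique` (logical).
#' @seealso [loadRuleTable()], [predictChemotype()]
#' @export
setClass("RuleTable", representation(rules = "data.frame"))

setValidity("RuleTable", function(object) {
  r <- object@rules
  if (!all(c("chemotype", "combination", "unique") %in% names(r))) {
    return("rules must have columns chemotype, combination, unique")
  }
  if (any(lengths(r$combination) == 0)) return("empty combination")
  recomputed <- recomputeUniqueness(r$combination, r$chemotype)
  if (!identical(recomputed, r$unique)) {
    return("uniqueness flags do not match the combinations")
  }
  TRUE
})
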