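#' Accessors for t2pks classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x An object of the documented class.
#' @name t2pks-accessors
NULL

#' @rdname t2pks-accessors
#' @export
setGeneric("referenceDomains", function(x) standardGeneric("referenceDomains"))
#' @rdname t2pks-accessors
#' @export
setGeneric("referenceSequences",
           function(x) standardGeneric("referenceSequences"))
#' @rdname t2pks-accessors
#' @export
setGeneric("genomeAccession", function(x) standardGeneric("genomeAccession"))
#' @rdname t2pks-accessors
#' @export
setGeneric("genomeGenes", function(x) standardGeneric("genomeGenes"))
#' @rdname t2pks-accessors
#' @export
setGeneric("genomeProteins", function(x) standardGeneric("genomeProteins"))
#' @rdname t2pks-accessors
#' @export
setGeneric("subfamilies", function(x) standardGeneric("subfamilies"))
#' @rdname t2pks-accessors
#' @export
setGeneric("pksClusters", function(x) standardGeneric("pksClusters"))
#' @rdname t2pks-accessors
#' @export
setGeneric("domainCalls", function(x) standardGeneric("domainCalls"))
#' @rdname t2pks-accessors
#' @export
setGeneric("clusterValid", function(x) standardGeneric("clusterValid"))
#' @rdname t2pks-accessors
#' @export
setGeneric("clusterChemotype", function(x) standardGeneric("clusterChemotype"))
#' @rdname t2pks-accessors
#' @export
setGeneric("clusterSpan", function(x) standardGeneric("clusterSpan"))
#' @rdname t2pks-accessors
#' @export
setGeneric("ruleRows", function(x) standardGeneric("ruleRows"))

#' @rdname t2pks-accessors
#' @export
setMethod("referenceDomains", "ReferenceSet", function(x) x@domains)
#' @rdname t2pks-accessors
#' @export
setMethod("referenceSequences", "ReferenceSet", function(x) x@sequences)
#' @rdname t2pks-accessors
#' @export
setMethod("genomeAccession", "GenomeRecord", function(x) x@accession)
#' @rdname t2pks-accessors
#' @export
setMethod("genomeAccession", "MiningResult", function(x) x@accession)
#' @rdname t2pks-accessors
#' @export
setMethod("genomeGenes", "GenomeRecord", function(x) x@genes)
#' @rdname t2pks-accessors
#' @export
setMethod("genomeProteins", "GenomeRecord", function(x) x@proteins)
#' @rdname t2pks-accessors
#' @export
setMethod("subfamilies", "SubfamilyTable", function(x) x@table)
#' @rdname t2pks-accessors
#' @export
setMethod("subfamilies", "ModelBank", function(x) names(x@models))
#' @rdname t2pks-accessors
#' @export
setMethod("pksClusters", "MiningResult", function(x) x@clusters)
#' @rdname t2pks-accessors
#' @export
setMethod("domainCalls", "MiningResult", function(x) x@calls)
#' @rdname t2pks-accessors
#' @export
setMethod("domainCalls", "PksCluster", function(x) x@calls)
#' @rdname t2pks-accessors
#' @export
setMethod("clusterValid", "PksCluster", function(x) x@valid)
#' @rdname t2pks-accessors
#' @export
setMethod("clusterChemotype", "PksCluster", function(x) x@chemotype)
#' @rdname t2pks-accessors
#' @export
setMethod("clusterSpan", "PksCluster", function(x) {
  c(start = min(BiocGenerics::start(x@genes)),
    end = max(BiocGenerics::end(x@genes)))
})
#' @rdname t2pks-accessors
#' @export
setMethod("ruleRows", "RuleTable", function(x) x@rules)

setMethod("show", "ReferenceSet", function(object) {
  d <- object@domains
  cat("ReferenceSet:", nrow(d), "domains on",
      length(unique(d$gene_name)), "proteins,",
      length(unique(subfamilyKey(d$pks_class, d$subfamily))),
      "subfamilies\n")
  print(table(factor(d$pks_class, levels = PKS_CLASSES)))
})

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord", object@accession,
      if (nzchar(object@organism)) paste0("(", object@organism, ")") else "",
      "\n  ", length(object@genes), "genes,", object@lengthBp, "bp",
      if (object@syntheticCoords) " [synthetic coordinates]" else "", "\n")
})

setMethod("show", "SubfamilyTable", function(object) {
  cat("SubfamilyTable:", nrow(object@table), "subfamilies",
      sprintf("(min identity %.0f%%, min coverage %.2f)\n",
              object@minIdentity, object@minCoverage))
  print(object@table[, c("pks_class", "subfamily", "n_members", "mean_length")])
})

setMethod("show", "ModelBank", function(object) {
  m <- vapply(object@models, function(x) x$method, "")
  cat("ModelBank:", length(m), "subfamily models, policy", object@policy, "\n")
  print(table(m))
})

setMethod("show", "ChemotypePrediction", function(object) {
  cat("ChemotypePrediction:", object@chemotype,
      paste0("[", object@rulePath,
             if (object@ambiguous) ", ambiguous" else "", "]"),
      "\n  signature: {", paste(object@signature, collapse = ", "), "}\n")
})

setMethod("show", "PksCluster", function(object) {
  sp <- clusterSpan(object)
  cat("PksCluster", object@clusterId, "on", object@accession, "\n  ",
      length(object@genes), "genes,", sp["start"], "-", sp["end"], "bp,",
      if (object@valid) "valid (KS+CLF)" else "invalid", "\n  domains:",
      paste(subfamilyKey(object@calls$pks_class, object@calls$subfamily),
            collapse = " "), "\n  chemotype:", object@chemotype@chemotype, "\n")
})

setMethod("show", "MiningResult", function(object) {
  nv <- sum(vapply(object@clusters, clusterValid, TRUE))
  cat("MiningResult for", object@accession, "\n  ",
      length(object@clusters), "clusters (", nv, "valid ),",
      object@nPksProteins, "type II PKS proteins,",
      nrow(object@novel), "newly annotated\n")
})

setMethod("show", "RuleTable", function(object) {
  r <- object@rules
  cat("RuleTable:", nrow(r), "rules,", sum(r$unique), "unique\n")
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-8s {%s} %s\n", r$chemotype[i],
                paste(r$combination[[i]], collapse = ", "),
                if (r$unique[i]) "unique" else "overlapped"))
  }
})
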