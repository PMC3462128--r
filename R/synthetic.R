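# Seeded generators for synthetic protein families, decoy sequences,
# reference sets with the published subfamily layout, and genomes with
# planted type II PKS clusters. Everything is deterministic given the seed,
# so the whole pipeline is testable without downloading any database.

# Robinson-Robinson style background amino-acid frequencies.
AA_BACKGROUND <- c(A = .078, C = .019, D = .054, E = .063, F = .039,
                   G = .074, H = .022, I = .051, K = .057, L = .090,
                   M = .022, N = .045, P = .052, Q = .043, R = .051,
                   S = .071, T = .058, V = .064, W = .013, Y = .032)

randomProtein <- function(length, composition = "uniform") {
  p <- if (composition == "background") {
    AA_BACKGROUND[AA_STANDARD] / sum(AA_BACKGROUND)
  } else rep(1 / 20, 20)
  paste(sample(AA_STANDARD, length, replace = TRUE, prob = p),
        collapse = "")
}

mutateProtein <- function(seq, substitutionRate = 0.1, indelRate = 0) {
  chars <- strsplit(as.character(seq), "")[[1]]
  out <- character(0)
  for (ch in chars) {
    r <- stats::runif(1)
    if (r < indelRate / 2) next                      # deletion
    if (r < indelRate) {                              # insertion before site
      out <- c(out, sample(AA_STANDARD, 1))
    }
    if (stats::runif(1) < substitutionRate) {
      ch <- sample(setdiff(AA_STANDARD, ch), 1)
    }
    out <- c(out, ch)
  }
  if (length(out) == 0) out <- sample(AA_STANDARD, 1)
  paste(out, collapse = "")
}

#' Generate a synthetic protein family
#'
#' Descendants of a random ancestor, mutated independently at the given
#' per-site substitution and indel rates. Deterministic per seed.
#'
#' @param nMembers Number of members (>= 1).
#' @param ancestorLength Ancestor length in residues.
#' @param substitutionRate Per-site substitution probability in [0, 1).
#' @param indelRate Per-site indel probability in [0, 1) (split evenly
#'   between insertion and deletion).
#' @param seed Integer seed.
#' @param ancestor Optional explicit ancestor sequence (overrides
#'   `ancestorLength`).
#' @param prefix Member name prefix.
#' @param composition `"uniform"` or `"background"` residue frequencies
#'   for the ancestor.
#' @return Named `AAStringSet` with attribute `"ancestor"`.
#' @export
generateFamily <- function(nMembers, ancestorLength = 200,
                           substitutionRate = 0.1, indelRate = 0.01,
                           seed = 1, ancestor = NULL, prefix = "fam",
                           composition = "uniform") {
  stopifnot(nMembers >= 1, substitutionRate >= 0, substitutionRate < 1,
            indelRate >= 0, indelRate < 1)
  withSeed(seed, {
    if (is.null(ancestor)) {
      ancestor <- randomProtein(ancestorLength, composition)
    }
    members <- vapply(seq_len(nMembers), function(i) {
      mutateProtein(ancestor, substitutionRate, indelRate)
    }, "")
    out <- Biostrings::AAStringSet(stats::setNames(
      members, sprintf("%s_%02d", prefix, seq_len(nMembers))))
    attr(out, "ancestor") <- as.character(ancestor)
    out
  })
}

#' Generate negative (decoy) sequences
#'
#' `n` i.i.d. random proteins drawn from background residue frequencies;
#' when `positives` are supplied, a residue-shuffled copy of each positive
#' is appended (identical composition, destroyed homology).
#'
#' @param n Number of random decoys.
#' @param lengths Length (recycled) of the random decoys.
#' @param seed Integer seed.
#' @param positives Optional named `AAStringSet` to shuffle.
#' @param composition `"uniform"` or `"background"`.
#' @return Named `AAStringSet` (`decoy_*` then `shuf_*`).
#' @export
generateNegatives <- function(n, lengths = 300, seed = 1, positives = NULL,
                              composition = "uniform") {
  withSeed(seed, {
    lengths <- rep_len(lengths, n)
    decoys <- vapply(seq_len(max(n, 0)), function(i) {
      randomProtein(lengths[i], composition)
    }, "")
    names(decoys) <- sprintf("decoy_%03d", seq_len(max(n, 0)))
    shuf <- character(0)
    if (!is.null(positives)) {
      shuf <- vapply(as.character(positives), shuffleResidues, "")
      names(shuf) <- paste0("shuf_", names(positives))
    }
    Biostrings::AAStringSet(c(decoys, shuf))
  })
}

#' The published subfamily layout of the reference set
#'
#' One row per (class, subfamily) with the member count and mean domain
#' length of the curated 308-domain reference set: the layout synthetic
#' reference sets reproduce and unknown (class, subfamily) pairs are
#' validated against.
#'
#' @return `data.frame` with columns `pks_class`, `subfamily`, `n`,
#'   `mean_length`.
#' @export
tableOneLayout <- function() {
  data.frame(
    pks_class = c("KS", "CLF", "ACP", "KR", "KR", "ARO", "ARO", "ARO",
                  "CYC", "CYC", "CYC", "CYC", "CYC", "CYC", "KSIII",
                  "KSIII", "AL", "AT", "MCAT", "TE"),
    subfamily = c("a", "a", "a", "a", "b", "a", "b", "c",
                  "a", "b", "c", "d", "e", "f", "a", "b", "a", "a", "a",
                  "a"),
    n = c(43L, 43L, 44L, 25L, 5L, 28L, 28L, 11L,
          11L, 10L, 19L, 6L, 5L, 6L, 4L, 3L, 3L, 10L, 3L, 1L),
    mean_length = c(416, 407, 78, 214, 204, 132, 143, 134,
                    93, 235, 102, 176, 121, 127, 218, 231, 389, 320, 309,
                    232),
    stringsAsFactors = FALSE)
}

# Chemotypes whose rules use a given subfamily key, in rule-table order.
chemotypesUsing <- function(key, rt = loadRuleTable()) {
  r <- ruleRows(rt)
  unique(r$chemotype[vapply(r$combination, function(cc) key %in% cc, TRUE)])
}

#' Generate a synthetic reference set with the published layout
#'
#' Emits one synthetic protein family per subfamily, sized and sampled to
#' the published layout (20 subfamilies, 308 domains on 280 proteins:
#' the ARO a and ARO b subfamilies are paired into didomain proteins
#' sharing a gene name). Each subfamily descends from its own random
#' ancestor, so subfamilies are mutually unrelated but internally cohesive
#' — the regime in which threshold calibration against the labeled
#' partition is meaningful. ARO/CYC members are labeled round-robin with
#' the chemotypes whose combination rules use their subfamily.
#'
#' @param seed Integer seed.
#' @param layout Subfamily layout (default [tableOneLayout()]).
#' @param substitutionRate Within-family substitution rate (default 0.08,
#'   i.e. roughly 85% within-family identity).
#' @param indelRate Within-family indel rate.
#' @return A [ReferenceSet].
#' @export
generateReferenceSet <- function(seed = 1, layout = tableOneLayout(),
                                 substitutionRate = 0.08,
                                 indelRate = 0.005) {
  rt <- loadRuleTable()
  rows <- list()
  seqs <- character(0)
  for (i in seq_len(nrow(layout))) {
    cls <- layout$pks_class[i]; sub <- layout$subfamily[i]
    key <- subfamilyKey(cls, sub)
    fam <- generateFamily(layout$n[i], layout$mean_length[i],
                          substitutionRate, indelRate,
                          seed = seed + 1009L * i,
                          prefix = tolower(paste0(cls, sub)))
    ids <- paste0(tolower(cls), sub, "_", sprintf("%02d", seq_len(layout$n[i])))
    chems <- chemotypesUsing(key, rt)
    chem <- if (length(chems) == 0) rep(NA_character_, layout$n[i]) else {
      rep_len(chems, layout$n[i])
    }
    gene <- if (cls == "ARO" && sub %in% c("a", "b")) {
      # didomain aromatases: the a and b halves share one protein
      paste0("aro_ab_", sprintf("%02d", seq_len(layout$n[i])))
    } else ids
    src <- ifelse(is.na(chem), paste0("cluster_", key),
                  paste0("cluster_", gsub("[^A-Za-z]", "", tolower(chem)),
                         "_", rep_len(seq_len(3), layout$n[i])))
    rows[[i]] <- data.frame(domain_id = ids, gene_name = gene,
                            pks_class = cls, subfamily = sub,
                            source_cluster = src, chemotype = chem,
                            stringsAsFactors = FALSE)
    seqs <- c(seqs, stats::setNames(as.character(fam), ids))
  }
  domains <- do.call(rbind, rows)
  rownames(domains) <- NULL
  new("ReferenceSet", sequences = Biostrings::AAStringSet(seqs),
      domains = domains)
}

#' Generate a chemotype-aware fixture reference set
#'
#' A compact reference set for end-to-end mining and homolog-vote tests:
#' each requested subfamily carries one sub-lineage per chemotype that uses
#' it (sub-lineages descend from independent ancestors, so homologs of a
#' query are confined to its own chemotype's lineage at stringent
#' e-values), and subfamilies used by no rule carry a single lineage. This
#' deliberately trades the within-subfamily cohesion of
#' [generateReferenceSet()] for vote separability; see the package
#' vignette.
#'
#' @param seed Integer seed.
#' @param subfamilies Subfamily keys to include (default: the minimal PKS
#'   classes plus every ARO/CYC subfamily used by the rule table).
#' @param nPerLineage Members per (subfamily, chemotype) lineage.
#' @param memberLength Residues per member (default 150).
#' @param substitutionRate Within-lineage substitution rate.
#' @return A [ReferenceSet].
#' @export
buildChemotypeReference <- function(seed = 7,
                                    subfamilies = NULL,
                                    nPerLineage = 6, memberLength = 150,
                                    substitutionRate = 0.06) {
  rt <- loadRuleTable()
  if (is.null(subfamilies)) {
    subfamilies <- c("KS_a", "CLF_a", "ACP_a", "KR_a",
                     sort(unique(unlist(ruleRows(rt)$combination))))
  }
  rows <- list(); seqs <- character(0)
  for (i in seq_along(subfamilies)) {
    key <- subfamilies[i]
    kk <- splitSubfamilyKey(key)
    chems <- chemotypesUsing(key, rt)
    lineages <- if (length(chems) == 0) list(NA_character_) else
      as.list(chems)
    for (j in seq_along(lineages)) {
      chem <- lineages[[j]]
      tag <- if (is.na(chem)) "core" else
        gsub("[^a-z]", "", tolower(chem))
      prefix <- paste0(tolower(kk$pks_class), kk$subfamily, "_", tag)
      fam <- generateFamily(nPerLineage, memberLength, substitutionRate,
                            indelRate = 0,
                            seed = seed + 2003L * i + 97L * j,
                            prefix = prefix)
      rows[[length(rows) + 1L]] <- data.frame(
        domain_id = names(fam), gene_name = names(fam),
        pks_class = kk$pks_class, subfamily = kk$subfamily,
        source_cluster = paste0("cluster_", tag),
        chemotype = chem, stringsAsFactors = FALSE)
      seqs <- c(seqs, stats::setNames(as.character(fam), names(fam)))
    }
  }
  domains <- do.call(rbind, rows)
  rownames(domains) <- NULL
  new("ReferenceSet", sequences = Biostrings::AAStringSet(seqs),
      domains = domains)
}

#' Plant a synthetic genome with known type II PKS clusters
#'
#' Builds a genome whose CDS translations are drawn (with light mutation)
#' from a reference set's subfamily members at specified positions, plus
#' unrelated decoy genes, together with the truth table the miner is
#' expected to recover: cluster spans, KS+CLF validity, and the chemotype
#' implied by the rule table (the planted lineage's chemotype for
#' overlapped combinations).
#'
#' @param spec List with elements:
#'   \describe{
#'     \item{`clusters`}{list of cluster specs; each a list with
#'       `subfamilies` (character vector of keys), optional `chemotype`
#'       (lineage to draw ARO/CYC members from), optional `gaps`
#'       (intervening bp between consecutive genes, length
#'       `length(subfamilies) - 1`, default 200), optional `strands`.}
#'     \item{`interClusterGap`}{bp between consecutive clusters
#'       (default 20000; must be >= the chaining threshold to keep
#'       clusters distinct).}
#'     \item{`decoyGenes`}{number of unrelated decoy genes appended after
#'       the last cluster (default 5).}
#'     \item{`decoyLength`}{decoy protein length (default 120).}
#'   }
#' @param reference A [ReferenceSet] (typically
#'   [buildChemotypeReference()]).
#' @param seed Integer seed.
#' @param drawRate Substitution rate applied to drawn members
#'   (default 0.03).
#' @param accession,organism,lineage Genome metadata.
#' @return List with `genome` (a [GenomeRecord]) and `truth`
#'   (`data.frame`: `cluster_id`, `start`, `end`, `n_genes`,
#'   `subfamilies`, `valid`, `chemotype`).
#' @export
plantGenome <- function(spec, reference, seed = 1, drawRate = 0.03,
                        accession = "SYNTH1",
                        organism = "Synthetica exempli",
                        lineage = data.frame(
                          rank = c("order", "suborder"),
                          name = c("Actinomycetales", "Frankineae"),
                          stringsAsFactors = FALSE)) {
  d <- referenceDomains(reference)
  refSeqs <- referenceSequences(reference)
  rt <- loadRuleTable()
  interGap <- spec$interClusterGap %||% 20000
  decoyGenes <- spec$decoyGenes %||% 5
  decoyLength <- spec$decoyLength %||% 120
  withSeed(seed, {
    genes <- list(); prots <- character(0); truth <- list()
    pos <- 501; geneNo <- 0
    for (ci in seq_along(spec$clusters)) {
      cs <- spec$clusters[[ci]]
      keys <- cs$subfamilies
      gaps <- cs$gaps %||% rep(200, max(length(keys) - 1, 0))
      strands <- cs$strands %||% rep("+", length(keys))
      stopifnot(length(gaps) == max(length(keys) - 1, 0))
      clStart <- NA; clEnd <- NA
      for (gi in seq_along(keys)) {
        kk <- splitSubfamilyKey(keys[gi])
        cand <- d$pks_class == kk$pks_class & d$subfamily == kk$subfamily
        if (!is.null(cs$chemotype) && kk$pks_class %in% c("ARO", "CYC") &&
            any(cand & !is.na(d$chemotype) &
                  d$chemotype == cs$chemotype)) {
          cand <- cand & !is.na(d$chemotype) & d$chemotype == cs$chemotype
        }
        candIdx <- which(cand)
        if (length(candIdx) == 0) stop("no reference member for ", keys[gi])
        pick <- candIdx[sample.int(length(candIdx), 1)]
        prot <- mutateProtein(refSeqs[[pick]], drawRate, 0)
        geneNo <- geneNo + 1
        gid <- sprintf("g%03d", geneNo)
        end <- pos + 3 * nchar(prot) - 1
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, start = pos, end = end, strand = strands[gi],
          locus_tag = sprintf("SYN_%04d", geneNo),
          product = "hypothetical protein", stringsAsFactors = FALSE)
        prots[gid] <- prot
        if (gi == 1) clStart <- pos
        clEnd <- end
        pos <- end + (if (gi < length(keys)) gaps[gi] else interGap) + 1
      }
      sig <- sort(unique(keys[grepl("^(ARO|CYC)_", keys)]))
      r <- ruleRows(rt)
      ruleKeys <- vapply(r$combination, paste, "", collapse = ",")
      hit <- which(ruleKeys == paste(sig, collapse = ","))
      chem <- if (length(hit) == 0) UNCLASSIFIED
      else if (length(hit) == 1 && r$unique[hit]) r$chemotype[hit]
      else cs$chemotype %||% UNCLASSIFIED
      valid <- ("KS" %in% splitSubfamilyKey(keys)$pks_class) &&
        ("CLF" %in% splitSubfamilyKey(keys)$pks_class)
      if (!valid) chem <- UNCLASSIFIED # invalid clusters are never predicted
      truth[[ci]] <- data.frame(
        cluster_id = paste0("cluster_", ci), start = clStart, end = clEnd,
        n_genes = length(keys),
        subfamilies = paste(keys, collapse = ","),
        valid = valid, chemotype = chem, stringsAsFactors = FALSE)
    }
    for (di in seq_len(decoyGenes)) {
      prot <- randomProtein(decoyLength)
      geneNo <- geneNo + 1
      gid <- sprintf("g%03d", geneNo)
      end <- pos + 3 * nchar(prot) - 1
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, start = pos, end = end, strand = "+",
        locus_tag = sprintf("SYN_%04d", geneNo),
        product = "hypothetical protein", stringsAsFactors = FALSE)
      prots[gid] <- prot
      pos <- end + 2001
    }
    genes <- do.call(rbind, genes)
    genome <- makeGenomeRecord(accession, organism = organism,
                               lineage = lineage, genes = genes,
                               proteins = Biostrings::AAStringSet(prots),
                               lengthBp = max(genes$end) + 500,
                               syntheticCoords = FALSE)
    list(genome = genome, truth = do.call(rbind, truth))
  })
}
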