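# Reading and writing the formats the pipeline touches: protein FASTA,
# GenBank flat files, the labeled reference set (TSV + FASTA) and the
# mining reports (GFF3 + TSV). Coordinates are 1-based inclusive
# everywhere (GenBank convention), inherited by the GFF3 output.

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

# Residues tolerated on input: the standard 20 plus ambiguity codes, which
# are retained in storage and masked to X only for alignment scoring.
AA_INPUT <- c(AA_STANDARD, "X", "B", "Z", "J", "U", "O")

checkProteinAlphabet <- function(seqs, what = "record") {
  chars <- toupper(as.character(seqs))
  chars <- sub("\\*+$", "", chars)
  for (i in seq_along(chars)) {
    if (!nzchar(chars[i])) {
      stop("empty protein sequence in ", what, " '", names(seqs)[i], "'")
    }
    bad <- setdiff(unique(strsplit(chars[i], "")[[1]]), AA_INPUT)
    if (length(bad) > 0) {
      stop("non-amino-acid characters (", paste(bad, collapse = ", "),
           ") in ", what, " '", names(seqs)[i], "'")
    }
  }
  Biostrings::AAStringSet(stats::setNames(chars, names(seqs)))
}

makeGenomeRecord <- function(accession, organism = "",
                             lineage = data.frame(rank = character(0),
                                                  name = character(0)),
                             genes, proteins, lengthBp,
                             syntheticCoords = FALSE) {
  gr <- GRanges(seqnames = rep(accession, nrow(genes)),
                ranges = IRanges(start = genes$start, end = genes$end),
                strand = genes$strand)
  mcols(gr)$gene_id <- genes$gene_id
  mcols(gr)$locus_tag <- genes$locus_tag
  mcols(gr)$product <- genes$product
  if (nrow(genes) > 0) proteins <- proteins[genes$gene_id]
  else proteins <- Biostrings::AAStringSet()
  new("GenomeRecord", accession = accession, organism = organism,
      lineage = lineage, genes = gr, proteins = proteins,
      lengthBp = lengthBp, syntheticCoords = syntheticCoords)
}

#' Read a protein FASTA as a genome record with synthetic coordinates
#'
#' Plain protein FASTA carries no genomic coordinates, but cluster chaining
#' needs positions; genes are therefore laid out in input order with a
#' configurable inter-gene spacing and the record is flagged as carrying
#' synthetic coordinates (the flag propagates into clusters and reports).
#'
#' @param path FASTA file of amino-acid sequences.
#' @param spacing Synthetic inter-gene gap in bp (default 1000).
#' @param accession Accession for the record (default: the file name).
#' @return A [GenomeRecord] with `syntheticCoords = TRUE`.
#' @export
readProteinFasta <- function(path, spacing = 1000,
                             accession = tools::file_path_sans_ext(
                               basename(path))) {
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) Biostrings::BStringSet())
  if (length(seqs) == 0) {
    warning("no sequences in '", path, "'")
    return(makeGenomeRecord(
      accession, genes = data.frame(gene_id = character(0),
                                    start = integer(0), end = integer(0),
                                    strand = character(0),
                                    locus_tag = character(0),
                                    product = character(0)),
      proteins = Biostrings::AAStringSet(), lengthBp = 0,
      syntheticCoords = TRUE))
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- checkProteinAlphabet(seqs, what = "FASTA record")
  ntLen <- 3 * Biostrings::width(seqs)
  # gap between consecutive gene bodies is exactly `spacing` bp
  starts <- cumsum(c(1, utils::head(ntLen + spacing, -1)))
  genes <- data.frame(gene_id = names(seqs), start = starts,
                      end = starts + ntLen - 1, strand = "+",
                      locus_tag = NA_character_, product = NA_character_,
                      stringsAsFactors = FALSE)
  makeGenomeRecord(accession, genes = genes, proteins = seqs,
                   lengthBp = max(genes$end), syntheticCoords = TRUE)
}

parseGenBankLocation <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  core <- gsub("[^0-9.]", "", loc)
  m <- regmatches(core, regexec("^([0-9]+)\\.\\.([0-9]+)$", core))[[1]]
  if (length(m) != 3) return(NULL)
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

#' Read a GenBank flat file
#'
#' Minimal parser for GenBank records with CDS features: coordinates are
#' taken 1-based inclusive as printed, strand from `complement(...)`
#' notation, proteins from `/translation` qualifiers (or translated from
#' the ORIGIN sequence when absent), lineage from the ORGANISM block with
#' ranks inferred from the standard bacterial suffixes (-ales order,
#' -ineae suborder, -aceae family). CDS features that cannot be translated
#' are skipped with a warning; a record without any usable CDS is an error.
#'
#' @param path GenBank flat file.
#' @return A [GenomeRecord].
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  accession <- sub("^ACCESSION\\s+", "",
                   grep("^ACCESSION", lines, value = TRUE)[1])
  if (is.na(accession)) {
    accession <- strsplit(sub("^LOCUS\\s+", "",
                              grep("^LOCUS", lines, value = TRUE)[1]),
                          "\\s+")[[1]][1]
  }
  lenBp <- suppressWarnings(as.numeric(
    sub("^LOCUS\\s+\\S+\\s+(\\d+)\\s+bp.*$", "\\1",
        grep("^LOCUS", lines, value = TRUE)[1])))
  organism <- ""
  lineage <- data.frame(rank = character(0), name = character(0))
  orgIdx <- grep("^\\s{2}ORGANISM", lines)
  if (length(orgIdx) > 0) {
    organism <- trimws(sub("^\\s{2}ORGANISM\\s*", "", lines[orgIdx[1]]))
    j <- orgIdx[1] + 1
    linLines <- character(0)
    while (j <= length(lines) && grepl("^\\s{8,}", lines[j])) {
      linLines <- c(linLines, trimws(lines[j])); j <- j + 1
    }
    nm <- trimws(strsplit(gsub("\\.$", "", paste(linLines, collapse = " ")),
                          ";")[[1]])
    nm <- nm[nzchar(nm)]
    if (length(nm) > 0) {
      rk <- ifelse(grepl("ales$", nm), "order",
                   ifelse(grepl("ineae$", nm), "suborder",
                          ifelse(grepl("aceae$", nm), "family", "clade")))
      lineage <- data.frame(rank = rk, name = nm, stringsAsFactors = FALSE)
    }
  }
  # ORIGIN sequence (may be absent when all CDS carry translations)
  oriIdx <- grep("^ORIGIN", lines)
  genomeSeq <- NULL
  if (length(oriIdx) > 0) {
    body <- lines[(oriIdx[1] + 1):length(lines)]
    body <- body[!grepl("^//", body)]
    genomeSeq <- toupper(gsub("[^a-zA-Z]", "", paste(body, collapse = "")))
  }
  featIdx <- grep("^FEATURES", lines)
  stopifnot(length(featIdx) > 0)
  featEnd <- if (length(oriIdx) > 0) oriIdx[1] - 1 else length(lines)
  feat <- lines[(featIdx[1] + 1):featEnd]
  cdsStarts <- grep("^\\s{5}CDS\\s", feat)
  if (length(cdsStarts) == 0) stop("no CDS features in '", path, "'")
  keyStarts <- grep("^\\s{5}\\S", feat)
  genes <- list(); prots <- character(0)
  for (k in seq_along(cdsStarts)) {
    i0 <- cdsStarts[k]
    i1 <- min(c(keyStarts[keyStarts > i0] - 1, length(feat)))
    block <- feat[i0:i1]
    loc <- parseGenBankLocation(trimws(sub("^\\s{5}CDS\\s+", "", block[1])))
    if (is.null(loc)) {
      warning("skipping CDS with unsupported location: ", trimws(block[1]))
      next
    }
    txt <- paste(trimws(block[-1]), collapse = " ")
    getQual <- function(q) {
      m <- regmatches(txt, regexec(sprintf('/%s="([^"]*)"', q), txt))[[1]]
      if (length(m) == 2) gsub("\\s+", if (q == "translation") "" else " ",
                               m[2]) else NA_character_
    }
    translation <- getQual("translation")
    if (is.na(translation)) {
      if (is.null(genomeSeq) ||
          (loc$end - loc$start + 1) %% 3 != 0) {
        warning("skipping untranslatable CDS at ", loc$start, "..", loc$end)
        next
      }
      nt <- Biostrings::DNAString(substr(genomeSeq, loc$start, loc$end))
      if (loc$strand == "-") nt <- Biostrings::reverseComplement(nt)
      translation <- sub("\\*$", "",
                         as.character(Biostrings::translate(nt)))
    }
    gid <- getQual("protein_id")
    if (is.na(gid)) gid <- getQual("locus_tag")
    if (is.na(gid)) gid <- sprintf("cds_%03d", k)
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gid, start = loc$start, end = loc$end,
      strand = loc$strand, locus_tag = getQual("locus_tag"),
      product = getQual("product"), stringsAsFactors = FALSE)
    prots[gid] <- translation
  }
  if (length(genes) == 0) stop("no usable CDS features in '", path, "'")
  genes <- do.call(rbind, genes)
  proteins <- checkProteinAlphabet(
    Biostrings::AAStringSet(prots), what = "CDS")
  if (is.na(lenBp)) lenBp <- max(genes$end)
  makeGenomeRecord(accession, organism = organism, lineage = lineage,
                   genes = genes, proteins = proteins, lengthBp = lenBp,
                   syntheticCoords = FALSE)
}

# Reverse-translate a protein with a fixed codon per residue (synthetic
# genomes only; real codon usage is irrelevant to the miner).
AA_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT",
              X = "GCT", B = "GAT", Z = "GAA", J = "CTG", U = "TGT",
              O = "AAA")

reverseTranslate <- function(protein) {
  paste(AA_CODON[strsplit(toupper(as.character(protein)), "")[[1]]],
        collapse = "")
}

#' Write a genome record as a GenBank flat file
#'
#' Emits LOCUS/ACCESSION/ORGANISM headers, one CDS feature per gene with
#' `/locus_tag`, `/product` and `/translation` qualifiers
#' (`complement(...)` for minus-strand genes) and an ORIGIN section. The
#' nucleotide sequence under each gene is a fixed-codon reverse
#' translation of its protein; intergenic space is filled with `t`.
#'
#' @param genome A [GenomeRecord].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(genome, path) {
  g <- genomeGenes(genome)
  prot <- genomeProteins(genome)
  n <- genome@lengthBp
  seqChars <- rep("t", n)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     linear   BCT 01-JAN-2026",
                   genome@accession, as.integer(n)),
           sprintf("DEFINITION  %s.",
                   if (nzchar(genome@organism)) genome@organism else
                     genome@accession),
           sprintf("ACCESSION   %s", genome@accession),
           sprintf("SOURCE      %s", genome@organism),
           sprintf("  ORGANISM  %s", genome@organism))
  if (nrow(genome@lineage) > 0) {
    out <- c(out, paste0("            ",
                         paste(genome@lineage$name, collapse = "; "), "."))
  }
  out <- c(out, "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", as.integer(n)))
  wrapQual <- function(text) {
    # qualifier continuation lines: hard wrap (translations have no spaces)
    pos <- seq(1, nchar(text), by = 58)
    vapply(pos, function(p) {
      paste0("                     ", substr(text, p, min(p + 57,
                                                          nchar(text))))
    }, "")
  }
  for (i in seq_along(g)) {
    s <- BiocGenerics::start(g)[i]; e <- BiocGenerics::end(g)[i]
    st <- as.character(BiocGenerics::strand(g)[i])
    p <- as.character(prot[[i]])
    nt <- reverseTranslate(p)
    if (nchar(nt) != e - s + 1) {
      stop("gene ", mcols(g)$gene_id[i], " span does not match 3x protein ",
           "length")
    }
    if (st == "-") {
      nt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))
    }
    seqChars[s:e] <- strsplit(tolower(nt), "")[[1]]
    loc <- sprintf("%d..%d", s, e)
    if (st == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     CDS             %s", loc),
             sprintf('                     /protein_id="%s"',
                     mcols(g)$gene_id[i]))
    if (!is.na(mcols(g)$locus_tag[i])) {
      out <- c(out, sprintf('                     /locus_tag="%s"',
                            mcols(g)$locus_tag[i]))
    }
    if (!is.na(mcols(g)$product[i])) {
      out <- c(out, sprintf('                     /product="%s"',
                            mcols(g)$product[i]))
    }
    tr <- paste0('/translation="', p, '"')
    out <- c(out, wrapQual(tr))
  }
  out <- c(out, "ORIGIN")
  full <- paste(seqChars, collapse = "")
  for (pos in seq(1, n, by = 60)) {
    chunk <- substr(full, pos, min(pos + 59, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", pos, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Load the labeled reference set from TSV + FASTA
#'
#' Joins a domain table (columns `gene_name`, `pks_class`, `subfamily`;
#' optional `domain_id`, `source_cluster`, `chemotype`) with the matching
#' protein FASTA. FASTA ids must match the table's `domain_id` (or
#' `gene_name` when no `domain_id` column exists); orphans on either side
#' are an error. Every (class, subfamily) pair must be one of the 20 known
#' subfamilies unless `permissive = TRUE`.
#'
#' @param tsvPath Domain table (TSV, header row, "." for missing).
#' @param fastaPath Protein FASTA.
#' @param permissive Allow unknown (class, subfamily) pairs.
#' @return A [ReferenceSet].
#' @export
loadReferenceSet <- function(tsvPath, fastaPath, permissive = FALSE) {
  tab <- utils::read.delim(tsvPath, stringsAsFactors = FALSE,
                           na.strings = c("NA", "."))
  need <- c("gene_name", "pks_class", "subfamily")
  if (!all(need %in% names(tab))) {
    stop("reference TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$domain_id)) tab$domain_id <- tab$gene_name
  if (is.null(tab$source_cluster)) tab$source_cluster <- NA_character_
  if (is.null(tab$chemotype)) tab$chemotype <- NA_character_
  seqs <- Biostrings::readAAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  orphanTab <- setdiff(tab$domain_id, names(seqs))
  orphanFa <- setdiff(names(seqs), tab$domain_id)
  if (length(orphanTab) || length(orphanFa)) {
    stop("TSV/FASTA id mismatch; missing sequences: [",
         paste(orphanTab, collapse = ", "), "]; unlisted sequences: [",
         paste(orphanFa, collapse = ", "), "]")
  }
  if (!permissive) {
    known <- subfamilyKey(tableOneLayout()$pks_class,
                          tableOneLayout()$subfamily)
    got <- subfamilyKey(tab$pks_class, tab$subfamily)
    bad <- setdiff(got, known)
    if (length(bad) > 0) {
      stop("unknown (class, subfamily) pairs: ", paste(bad, collapse = ", "),
           " (use permissive = TRUE to keep them)")
    }
  }
  seqs <- checkProteinAlphabet(seqs[tab$domain_id], what = "reference")
  new("ReferenceSet", sequences = seqs,
      domains = tab[, c("domain_id", "gene_name", "pks_class", "subfamily",
                        "source_cluster", "chemotype")])
}

#' Write a reference set as TSV + FASTA
#'
#' Inverse of [loadReferenceSet()]; round trips are lossless.
#'
#' @param reference A [ReferenceSet].
#' @param tsvPath,fastaPath Output files.
#' @return Invisibly, the two paths.
#' @export
writeReferenceSet <- function(reference, tsvPath, fastaPath) {
  utils::write.table(referenceDomains(reference), tsvPath, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  Biostrings::writeXStringSet(referenceSequences(reference), fastaPath)
  invisible(c(tsvPath, fastaPath))
}

#' Write the mining report files for one genome
#'
#' Emits, under `outDir`:
#' \describe{
#'   \item{`<accession>_clusters.gff3`}{domain calls
#'     (`type = protein_match`) and cluster spans (`type = gene_cluster`),
#'     1-based inclusive coordinates.}
#'   \item{`<accession>_summary.tsv`}{the genome's summary row: organism,
#'     size, number of type II PKS proteins in valid clusters, chemotype
#'     tally.}
#'   \item{`<accession>_domains.tsv`}{one row per domain call: accession,
#'     cluster, protein id, predicted class, best homolog, e-value, start,
#'     end, direction, locus tag ("." for missing).}
#' }
#'
#' @param result A [MiningResult].
#' @param outDir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeMiningReport <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  acc <- result@accession
  gffPath <- file.path(outDir, paste0(acc, "_clusters.gff3"))
  sumPath <- file.path(outDir, paste0(acc, "_summary.tsv"))
  domPath <- file.path(outDir, paste0(acc, "_domains.tsv"))

  feats <- list()
  for (cl in pksClusters(result)) {
    sp <- clusterSpan(cl)
    gr <- GRanges(acc, IRanges(sp["start"], sp["end"]), strand = "*")
    mcols(gr)$source <- "t2pks"
    mcols(gr)$type <- "gene_cluster"
    mcols(gr)$score <- NA_real_
    mcols(gr)$ID <- cl@clusterId
    mcols(gr)$Parent <- NA_character_
    mcols(gr)$Note <- paste0(
      if (clusterValid(cl)) "valid" else "invalid", ";chemotype=",
      cl@chemotype@chemotype,
      if (cl@syntheticCoords) ";synthetic_coordinates" else "")
    feats[[length(feats) + 1L]] <- gr
    cc <- domainCalls(cl)
    for (i in seq_len(nrow(cc))) {
      m <- GRanges(acc, IRanges(cc$start[i], cc$end[i]),
                   strand = cc$strand[i])
      mcols(m)$source <- "t2pks"
      mcols(m)$type <- "protein_match"
      mcols(m)$score <- cc$score[i]
      mcols(m)$ID <- paste0(cl@clusterId, ".", cc$gene_id[i], ".",
                            subfamilyKey(cc$pks_class[i], cc$subfamily[i]))
      mcols(m)$Parent <- cl@clusterId
      mcols(m)$Note <- paste0("subfamily=",
                              subfamilyKey(cc$pks_class[i],
                                           cc$subfamily[i]),
                              ";method=", cc$method[i])
      feats[[length(feats) + 1L]] <- m
    }
  }
  if (length(feats) == 0) {
    writeLines("##gff-version 3", gffPath)
  } else {
    all <- suppressWarnings(do.call(c, feats))
    rtracklayer::export(all, gffPath, format = "gff3")
  }

  utils::write.table(genomeSummary(result), sumPath, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")

  rows <- list()
  for (cl in pksClusters(result)) {
    cc <- domainCalls(cl)
    if (nrow(cc) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      accession = acc, cluster = cl@clusterId, protein_id = cc$gene_id,
      predicted_class = subfamilyKey(cc$pks_class, cc$subfamily),
      homologs = cc$homolog, evalue = cc$evalue, start = cc$start,
      end = cc$end, direction = cc$strand, locus_tag = cc$locus_tag,
      stringsAsFactors = FALSE)
  }
  dom <- do.call(rbind, rows) %||% data.frame(
    accession = character(0), cluster = character(0),
    protein_id = character(0), predicted_class = character(0),
    homologs = character(0), evalue = numeric(0), start = integer(0),
    end = integer(0), direction = character(0), locus_tag = character(0))
  utils::write.table(dom, domPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(c(gffPath, sumPath, domPath))
}
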