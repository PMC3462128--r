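# Profile HMM construction and scoring via the HMMER 3 binaries
# (hmmbuild/hmmsearch), with MAFFT for the underlying multiple alignments.

#' Multiple alignment of a protein family
#'
#' Aligns family members with MAFFT (deterministic for a fixed input order).
#' A single sequence is returned as a trivial one-row alignment. Columns
#' with more than 50% gaps are flagged (not removed) in the
#' `"gapFlagged"` attribute.
#'
#' @param seqs Named `AAStringSet` (or character vector) of members.
#' @return An `AAStringSet` of equal-width aligned sequences with attribute
#'   `gapFlagged` (logical per column).
#' @export
buildMsa <- function(seqs) {
  seqs <- Biostrings::AAStringSet(seqs)
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (length(seqs) == 1) {
    aln <- seqs
  } else {
    checkTool("mafft")
    fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
    on.exit(unlink(c(fin, fout)))
    writeXStringSet(seqs, fin)
    status <- system2("mafft", c("--quiet", "--auto", shQuote(fin)),
                      stdout = fout, stderr = FALSE)
    if (status != 0) stop("mafft failed with status ", status)
    aln <- readAAStringSet(fout)
    names(aln) <- sub("\\s.*$", "", names(aln))
    aln <- aln[names(seqs)]
  }
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  attr(aln, "gapFlagged") <- colMeans(m == "-") > 0.5
  aln
}

#' Build a calibrated profile HMM for one subfamily
#'
#' Runs `hmmbuild` on the member alignment and calibrates a positive-call
#' threshold from the minimum bit score of the training members against
#' their own profile: `threshold = minTrain - max(margin, minTrain / 2)`.
#' The relative component matters because in-sample scores of small
#' alignments are optimistically inflated — a genuine family member held
#' out of training can score tens of bits below the lowest in-sample
#' score, while non-members score far below half of it. Every training
#' member scores at or above the threshold by construction.
#'
#' @param msa Aligned members from [buildMsa()] (an unaligned `AAStringSet`
#'   is aligned first).
#' @param name Profile name (typically the subfamily key).
#' @param margin Minimum margin in bits subtracted from the lowest
#'   training-member score (default 10; the effective margin is at least
#'   half that score).
#' @return List with `name`, `hmm` (the HMMER3 text profile, line vector),
#'   `threshold` (bits) and `trainScores`.
#' @export
buildProfile <- function(msa, name = "profile", margin = 10) {
  msa <- Biostrings::AAStringSet(msa)
  stopifnot(length(msa) >= 1)
  if (length(unique(Biostrings::width(msa))) > 1) msa <- buildMsa(msa)
  checkTool("hmmbuild")
  fin <- tempfile(fileext = ".afa"); fout <- tempfile(fileext = ".hmm")
  on.exit(unlink(c(fin, fout)))
  writeXStringSet(msa, fin)
  status <- system2("hmmbuild",
                    c("--amino", "-n", shQuote(name), shQuote(fout),
                      shQuote(fin)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("hmmbuild failed with status ", status)
  profile <- list(name = name, hmm = readLines(fout), threshold = -Inf,
                  trainScores = NULL)
  members <- Biostrings::AAStringSet(gsub("-", "",
                                          as.character(msa), fixed = TRUE))
  sc <- scoreProfiles(list(profile), members)
  scores <- stats::setNames(rep(NA_real_, length(members)), names(members))
  scores[sc$seq_id] <- sc$bits
  if (anyNA(scores)) stop("training member failed to score on its profile")
  profile$trainScores <- scores
  minTrain <- min(scores)
  profile$threshold <- minTrain - max(margin, minTrain / 2)
  profile
}

#' Score sequences against one or more profile HMMs
#'
#' Concatenates the given profiles into one HMM database and runs a single
#' `hmmsearch` over the sequences (effective database size fixed at 1000 so
#' e-values are comparable across runs). Per (profile, sequence) pair the
#' full-sequence bit score and the best domain's alignment/envelope
#' coordinates on the sequence are returned; pairs without a reported hit
#' are absent.
#'
#' @param profiles List of profiles from [buildProfile()] (or one profile).
#' @param seqs Named `AAStringSet` of query sequences.
#' @return `data.frame` with columns `profile`, `seq_id`, `bits`, `evalue`,
#'   `ali_from`, `ali_to`, `env_from`, `env_to`.
#' @export
scoreProfiles <- function(profiles, seqs) {
  if (!is.null(profiles$hmm)) profiles <- list(profiles)
  seqs <- Biostrings::AAStringSet(seqs)
  stopifnot(length(seqs) >= 1, all(nzchar(names(seqs))))
  if (any(Biostrings::width(seqs) == 0)) {
    stop("cannot score an empty sequence")
  }
  checkTool("hmmsearch")
  fhmm <- tempfile(fileext = ".hmm"); fseq <- tempfile(fileext = ".fa")
  fdom <- tempfile(fileext = ".domtbl")
  on.exit(unlink(c(fhmm, fseq, fdom)))
  writeLines(unlist(lapply(profiles, `[[`, "hmm")), fhmm)
  writeXStringSet(seqs, fseq)
  # --max disables the acceleration filters: at this problem scale the full
  # dynamic programming is cheap and keeps weak cross-lineage members visible
  status <- system2("hmmsearch",
                    c("--domtblout", shQuote(fdom), "--max", "-E", "1000",
                      "--domE", "1000", "-Z", "1000", "--domZ", "1000",
                      "--noali", shQuote(fhmm), shQuote(fseq)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("hmmsearch failed with status ", status)
  lines <- grep("^#", readLines(fdom), invert = TRUE, value = TRUE)
  empty <- data.frame(profile = character(0), seq_id = character(0),
                      bits = numeric(0), evalue = numeric(0),
                      ali_from = integer(0), ali_to = integer(0),
                      env_from = integer(0), env_to = integer(0))
  if (length(lines) == 0) return(empty)
  f <- strsplit(trimws(lines), "\\s+")
  hits <- data.frame(
    profile = vapply(f, `[`, "", 4L),
    seq_id = vapply(f, `[`, "", 1L),
    bits = as.numeric(vapply(f, `[`, "", 8L)),
    evalue = as.numeric(vapply(f, `[`, "", 7L)),
    dom_bits = as.numeric(vapply(f, `[`, "", 14L)),
    ali_from = as.integer(vapply(f, `[`, "", 18L)),
    ali_to = as.integer(vapply(f, `[`, "", 19L)),
    env_from = as.integer(vapply(f, `[`, "", 20L)),
    env_to = as.integer(vapply(f, `[`, "", 21L)),
    stringsAsFactors = FALSE)
  # keep the best-scoring domain per (profile, sequence)
  key <- paste(hits$profile, hits$seq_id, sep = "\r")
  hits <- hits[order(key, -hits$dom_bits), ]
  hits <- hits[!duplicated(paste(hits$profile, hits$seq_id, sep = "\r")), ]
  rownames(hits) <- NULL
  hits[, setdiff(names(hits), "dom_bits")]
}

#' Score one sequence against one profile
#'
#' @param profile A profile from [buildProfile()].
#' @param seq One amino-acid sequence.
#' @return List with `bits`, `evalue` and envelope coordinates, or `NULL`
#'   when the sequence does not hit the profile at all.
#' @export
scoreProfile <- function(profile, seq) {
  seq <- as.character(seq)
  if (!nzchar(seq)) stop("cannot score an empty sequence")
  res <- scoreProfiles(list(profile),
                       Biostrings::AAStringSet(c(query = seq)))
  if (nrow(res) == 0) return(NULL)
  as.list(res[1, c("bits", "evalue", "ali_from", "ali_to",
                   "env_from", "env_to")])
}
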