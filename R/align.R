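#' @importFrom Biostrings AAString AAStringSet pairwiseAlignment pid
#'   writeXStringSet readAAStringSet width pattern subject
#' @importFrom BiocGenerics score start end width strand
NULL

# Karlin-Altschul parameters for BLOSUM62 with affine gaps (open 11, extend 1),
# the standard gapped values. Used to turn raw local-alignment scores into
# e-values for homology searches; thresholds downstream are configurable so
# the exact constants are not load-bearing.
KA_LAMBDA <- 0.267
KA_K <- 0.041

substitutionMatrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# Ambiguity codes (B, Z, J, U, O, *) are kept in stored sequences but masked
# to X before scoring: the substitution matrices define X.
maskAmbiguous <- function(x) {
  gsub(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), "X",
       toupper(as.character(x)))
}

#' Optimal local (Smith-Waterman) alignment of two protein sequences
#'
#' Aligns two amino-acid sequences with affine gap penalties under a
#' substitution matrix and reports the optimal local score, the percent
#' identity over aligned columns, and the coverage of the shorter sequence.
#' A gap of length k costs `gapOpen + k * gapExtend`.
#'
#' @param a,b Amino-acid sequences (character or `AAString`); non-standard
#'   residues are masked to `X` for scoring.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gapOpen,gapExtend Gap opening/extension penalties (positive).
#' @param queryId,subjectId Optional ids carried into the result.
#' @return One-row `data.frame` with columns `query_id`, `subject_id`,
#'   `score`, `percent_identity` (0-100), `coverage` (0-1: aligned residues
#'   of the shorter sequence / its length).
#' @examples
#' alignLocal("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
#'            gapOpen = 0, gapExtend = 8)
#' @export
alignLocal <- function(a, b, matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                       queryId = "query", subjectId = "subject") {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("alignLocal: empty sequence")
  mat <- substitutionMatrix(matrix)
  pa <- pairwiseAlignment(AAString(maskAmbiguous(a)),
                          AAString(maskAmbiguous(b)),
                          type = "local", substitutionMatrix = mat,
                          gapOpening = gapOpen, gapExtension = gapExtend)
  alnA <- as.character(pattern(pa))
  alnB <- as.character(subject(pa))
  resA <- nchar(gsub("-", "", alnA, fixed = TRUE))
  resB <- nchar(gsub("-", "", alnB, fixed = TRUE))
  shorter <- if (nchar(a) <= nchar(b)) c(resA, nchar(a)) else c(resB, nchar(b))
  data.frame(query_id = queryId, subject_id = subjectId,
             score = score(pa), percent_identity = pid(pa),
             coverage = shorter[1] / shorter[2], stringsAsFactors = FALSE)
}

# Scores of one query against many references, score only (fast path used
# for SVM features, homology search and shuffled-decoy checks).
localScores <- function(query, refs, matrix = "BLOSUM62",
                        gapOpen = 11, gapExtend = 1) {
  if (length(refs) == 0) return(numeric(0))
  mat <- substitutionMatrix(matrix)
  refsm <- AAStringSet(vapply(as.character(refs), maskAmbiguous, ""))
  s <- pairwiseAlignment(refsm, AAString(maskAmbiguous(query)),
                         type = "local", substitutionMatrix = mat,
                         gapOpening = gapOpen, gapExtension = gapExtend,
                         scoreOnly = TRUE)
  stats::setNames(s, names(refs))
}

# Karlin-Altschul e-value of a raw local alignment score for a search space
# of m x n residues.
alignmentEvalue <- function(score, m, n, lambda = KA_LAMBDA, K = KA_K) {
  K * m * n * exp(-lambda * score)
}

#' All-pairs local-alignment hits within a sequence set
#'
#' Computes `alignLocal()` for every unordered pair of the set; the backbone
#' of the single-linkage homology clustering.
#'
#' @param seqs Named `AAStringSet` (or named character vector).
#' @inheritParams alignLocal
#' @return `data.frame` with one row per unordered pair.
#' @export
pairwiseHits <- function(seqs, matrix = "BLOSUM62", gapOpen = 11,
                         gapExtend = 1) {
  seqs <- AAStringSet(seqs)
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(seqs)
  if (n < 2) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      score = numeric(0), percent_identity = numeric(0),
                      coverage = numeric(0)))
  }
  pairs <- utils::combn(n, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    alignLocal(as.character(seqs[[i]]), as.character(seqs[[j]]),
               matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend,
               queryId = ids[i], subjectId = ids[j])
  })
  do.call(rbind, rows)
}
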