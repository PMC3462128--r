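# Independent oracles the implementation is checked against. These share no
# code with the package paths they verify.

# O(nm) affine-gap Smith-Waterman (gap of length k costs open + k * ext).
swOracle <- function(a, b, matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1) {
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  sub <- get(matrix, envir = e)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      X[i, j] <- max(M[i - 1, j] - gapOpen - gapExtend,
                     X[i - 1, j] - gapExtend)
      Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExtend,
                     Y[i, j - 1] - gapExtend)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + sub[A[i - 1], B[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# Union-find over explicit edges; returns the partition as a sorted list of
# sorted member vectors.
unionFindPartition <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(ids, find, "")
  out <- lapply(split(ids, roots), function(x) sort(unname(x)))
  unname(out[order(vapply(out, `[`, "", 1L))])
}

# Canonical form of a partition (list of member vectors) for set comparison.
canonicalPartition <- function(p) {
  p <- lapply(p, function(x) sort(unname(x)))
  unname(p[order(vapply(p, `[`, "", 1L))])
}

# Brute-force connected components of genes under "intervening bp < maxGap":
# full pairwise graph + BFS, no sorting tricks.
intervalComponentsOracle <- function(starts, ends, ids, maxGap) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    gap <- max(starts[i], starts[j]) - min(ends[i], ends[j]) - 1
    if (gap < maxGap) adj[i, j] <- TRUE
  }
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0))
    }
  }
  canonicalPartition(split(ids, comp))
}

# Direct arithmetic recomputation of the evaluation metrics.
metricsOracle <- function(tp, tn, fp, fn) {
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  ac <- (tp + tn) / (tp + tn + fp + fn)
  den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fn * fp) / den
  100 * c(SN = sn, SP = sp, AC = ac, MCC = mcc)
}
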