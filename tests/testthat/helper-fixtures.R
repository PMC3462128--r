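# Shared fixtures, built in code and memoized for the whole test run (the
# chemotype-aware reference and its trained bank are the expensive ones).

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

fixtureChemRef <- function() {
  cachedFixture("chemRef", buildChemotypeReference(seed = 7))
}

fixtureBank <- function() {
  cachedFixture("bank", trainModelBank(fixtureChemRef(), seed = 42))
}

# A compact three-class reference set for clustering tests (full layout is
# exercised in the acceptance suite).
fixtureSmallRef <- function() {
  cachedFixture("smallRef", {
    layout <- data.frame(
      pks_class = c("KS", "KR", "KR", "CYC", "CYC", "CYC"),
      subfamily = c("a", "a", "b", "a", "b", "c"),
      n = c(8L, 6L, 3L, 5L, 4L, 3L),
      mean_length = c(120, 110, 100, 90, 95, 100))
    generateReferenceSet(seed = 11, layout = layout)
  })
}

# A minimal genome wrapper for chaining tests: genes at given coordinates
# with dummy proteins (chaining never looks at sequences).
chainFixture <- function(starts, ends, maxGap = 15000) {
  n <- length(starts)
  ids <- sprintf("g%02d", seq_len(n))
  genes <- data.frame(gene_id = ids, start = starts, end = ends,
                      strand = "+", locus_tag = NA_character_,
                      product = NA_character_, stringsAsFactors = FALSE)
  prot <- Biostrings::AAStringSet(stats::setNames(
    rep("MKTAYIAKQR", n), ids))
  genome <- t2pks:::makeGenomeRecord("CHAIN1", genes = genes,
                                     proteins = prot,
                                     lengthBp = max(ends) + 10)
  calls <- data.frame(gene_id = ids, pks_class = "KS", subfamily = "a",
                      method = "HMM", score = 100, evalue = 1e-20,
                      dom_start = 1L, dom_end = 10L,
                      homolog = NA_character_, start = starts, end = ends,
                      strand = "+", locus_tag = NA_character_,
                      product = NA_character_, stringsAsFactors = FALSE)
  chainClusters(genome, calls, maxGap = maxGap)
}

# The planted-genome specifications used for end-to-end recovery: one per
# rule-table row (11), plus boundary and validity cases.
plantedSpecSuite <- function() {
  rt <- loadRuleTable()
  r <- ruleRows(rt)
  specs <- lapply(seq_len(nrow(r)), function(i) {
    list(clusters = list(list(
      subfamilies = c("KS_a", "CLF_a", "ACP_a", r$combination[[i]]),
      chemotype = r$chemotype[i])))
  })
  specs[[length(specs) + 1L]] <- list(clusters = list(list(
    subfamilies = c("KS_a", "CLF_a", "ACP_a"), gaps = c(5000, 14999))))
  specs[[length(specs) + 1L]] <- list(clusters = list(
    list(subfamilies = c("KS_a", "CLF_a")),
    list(subfamilies = c("ACP_a", "KR_a"))), interClusterGap = 15000)
  specs[[length(specs) + 1L]] <- list(clusters = list(
    list(subfamilies = c("KS_a", "KR_a"))))
  specs
}

# Mine one planted genome and compare spans, validity and chemotype with
# the planted truth; returns TRUE on exact recovery.
recoversTruth <- function(spec, reference, bank, seed) {
  pg <- plantGenome(spec, reference, seed = seed)
  res <- mineGenome(pg$genome, bank)
  cls <- pksClusters(res)
  if (length(cls) != nrow(pg$truth)) return(FALSE)
  got <- do.call(rbind, lapply(cls, function(cl) {
    sp <- clusterSpan(cl)
    data.frame(start = unname(sp["start"]), end = unname(sp["end"]),
               valid = clusterValid(cl),
               chemotype = cl@chemotype@chemotype)
  }))
  got <- got[order(got$start), ]
  want <- pg$truth[order(pg$truth$start),
                   c("start", "end", "valid", "chemotype")]
  isTRUE(all.equal(got, want, check.attributes = FALSE))
}

fixturePlanted <- function() {
  cachedFixture("planted", {
    spec <- list(clusters = list(list(
      subfamilies = c("KS_a", "CLF_a", "ACP_a", "ARO_a", "ARO_b", "CYC_a"),
      gaps = c(300, 2000, 500, 800, 1200))),
      decoyGenes = 6)
    plantGenome(spec, fixtureChemRef(), seed = 301)
  })
}
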