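test_that("identical sequences collapse to one cluster", {
  seqs <- Biostrings::AAStringSet(stats::setNames(
    rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", 5), paste0("s", 1:5)))
  part <- clusterSingleLinkage(seqs, minIdentity = 90, minCoverage = 0.9)
  expect_length(part, 1)
  expect_setequal(part[[1]], paste0("s", 1:5))
})

test_that("single-linkage equals a union-find oracle on random instances", {
  for (seed in c(3, 4, 5)) {
    fams <- c(generateFamily(4, 60, 0.08, 0, seed = seed, prefix = "a"),
              generateFamily(4, 60, 0.08, 0, seed = seed + 50, prefix = "b"),
              generateFamily(4, 60, 0.08, 0, seed = seed + 100, prefix = "c"))
    hits <- pairwiseHits(fams)
    for (minId in c(30, 60, 95)) {
      part <- clusterSingleLinkage(fams, minIdentity = minId,
                                   minCoverage = 0.5, hits = hits)
      keep <- hits$percent_identity >= minId & hits$coverage >= 0.5
      oracle <- unionFindPartition(
        names(fams), as.matrix(hits[keep, c("query_id", "subject_id")]))
      expect_equal(canonicalPartition(part), oracle,
                   info = paste("seed", seed, "minId", minId))
    }
  }
})

test_that("clustering output is a partition, ordered by size then member id", {
  fams <- c(generateFamily(5, 60, 0.05, 0, seed = 9, prefix = "x"),
            generateFamily(3, 60, 0.05, 0, seed = 19, prefix = "y"))
  part <- clusterSingleLinkage(fams, minIdentity = 60, minCoverage = 0.5)
  expect_setequal(unlist(part), names(fams))
  expect_equal(anyDuplicated(unlist(part)), 0L)
  expect_equal(lengths(part), sort(lengths(part), decreasing = TRUE))
})

test_that("lowering thresholds never increases the number of clusters", {
  fams <- c(generateFamily(4, 60, 0.15, 0, seed = 21, prefix = "m"),
            generateFamily(4, 60, 0.15, 0, seed = 22, prefix = "n"))
  hits <- pairwiseHits(fams)
  nClusters <- vapply(c(90, 70, 50, 30), function(id) {
    length(clusterSingleLinkage(fams, minIdentity = id, minCoverage = 0.5,
                                hits = hits))
  }, 0L)
  expect_true(all(diff(nClusters) <= 0))
  nByCov <- vapply(c(0.9, 0.7, 0.5), function(cov) {
    length(clusterSingleLinkage(fams, minIdentity = 40, minCoverage = cov,
                                hits = hits))
  }, 0L)
  expect_true(all(diff(nByCov) <= 0))
})

test_that("subfamily summary labels by size and reports mean lengths", {
  ref <- fixtureSmallRef()
  cal <- calibrateThresholds(ref, idGrid = c(30, 40, 50),
                             covGrid = c(0.5, 0.7))
  expect_true(cal$exact)
  tab <- subfamilies(cal$table)
  d <- referenceDomains(ref)
  expect_equal(nrow(tab), 6)
  # per class, sizes match the planted layout as multisets
  for (cls in unique(d$pks_class)) {
    expect_setequal(tab$n_members[tab$pks_class == cls],
                    as.integer(table(d$subfamily[d$pks_class == cls])))
    sz <- tab$n_members[tab$pks_class == cls]
    expect_equal(sz, sort(sz, decreasing = TRUE))
  }
  # mean length equals the arithmetic mean of member widths
  seqs <- referenceSequences(ref)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$mean_length[i],
                 mean(Biostrings::width(seqs[tab$member_ids[[i]]])))
  }
})

test_that("a singleton class yields one subfamily of size one", {
  seqs <- Biostrings::AAStringSet(c(te_1 = "MKTAYIAKQRQISFVKSHFSRQLEERLG"))
  st <- summarizeSubfamilies(list(TE = list("te_1")), seqs)
  tab <- subfamilies(st)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_members, 1L)
  expect_equal(tab$mean_length, 28)
})
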