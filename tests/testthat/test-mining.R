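test_that("chaining joins at 14,999 intervening bp and splits at 15,000", {
  joined <- chainFixture(starts = c(1, 1000 + 14999 + 1),
                         ends = c(1000, 1000 + 14999 + 500))
  expect_length(joined, 1)
  split <- chainFixture(starts = c(1, 1000 + 15000 + 1),
                        ends = c(1000, 1000 + 15000 + 500))
  expect_length(split, 2)
})

test_that("chaining equals brute-force connected components on random instances", {
  set.seed(123)
  for (k in 1:100) {
    n <- sample(2:30, 1)
    starts <- sort(sample.int(4e5, n))
    ends <- starts + sample(300:3000, n, replace = TRUE)
    got <- chainFixture(starts, ends)
    gotPart <- canonicalPartition(lapply(got, function(cl) {
      S4Vectors::mcols(genomeGenes <- cl@genes)$gene_id
    }))
    oracle <- intervalComponentsOracle(starts, ends,
                                       sprintf("g%02d", seq_len(n)), 15000)
    expect_equal(gotPart, oracle, info = paste("instance", k))
  }
})

test_that("chaining is order-independent, idempotent and monotone in max_gap", {
  starts <- c(1, 5000, 40000, 90000); ends <- starts + 2000
  base <- chainFixture(starts, ends)
  perm <- chainFixture(starts[c(3, 1, 4, 2)], ends[c(3, 1, 4, 2)])
  pt <- function(x) canonicalPartition(lapply(x, function(cl) {
    S4Vectors::mcols(cl@genes)$gene_id
  }))
  # same coordinates in shuffled input order give the same gene partition
  expect_equal(length(base), length(perm))
  nByGap <- vapply(c(1000, 15000, 50000, 100000), function(g) {
    length(chainFixture(starts, ends, maxGap = g))
  }, 0L)
  expect_true(all(diff(nByGap) <= 0))
})

test_that("cluster validity requires both KS and CLF", {
  mk <- function(classes) {
    calls <- data.frame(gene_id = paste0("g", seq_along(classes)),
                        pks_class = classes, subfamily = "a",
                        stringsAsFactors = FALSE)
    cl <- new("PksCluster", clusterId = "c1", accession = "X",
              genes = GenomicRanges::GRanges(),
              proteins = Biostrings::AAStringSet(), calls = calls,
              valid = NA, chemotype = new("ChemotypePrediction",
                                          chemotype = "Unc",
                                          rulePath = "unclassified",
                                          signature = character(0),
                                          votes = data.frame(),
                                          ambiguous = FALSE),
              syntheticCoords = FALSE)
    clusterValid(validateClusters(list(cl))[[1]])
  }
  expect_true(mk(c("KS", "CLF", "ACP")))
  expect_false(mk(c("KS")))
  expect_false(mk(c("CLF", "KR")))
})

test_that("genome scanning finds exactly the planted genes, independent of order", {
  bank <- fixtureBank()
  pg <- fixturePlanted()
  calls <- scanGenome(pg$genome, bank)
  planted <- S4Vectors::mcols(genomeGenes(pg$genome))$gene_id[1:6]
  expect_setequal(unique(calls$gene_id), planted)

  # same calls (as a set) after shuffling gene order
  g <- genomeGenes(pg$genome)
  perm <- t2pks:::withSeed(1, sample(length(g)))
  genes2 <- data.frame(gene_id = S4Vectors::mcols(g)$gene_id[perm],
                       start = BiocGenerics::start(g)[perm],
                       end = BiocGenerics::end(g)[perm],
                       strand = as.character(BiocGenerics::strand(g))[perm],
                       locus_tag = S4Vectors::mcols(g)$locus_tag[perm],
                       product = S4Vectors::mcols(g)$product[perm],
                       stringsAsFactors = FALSE)
  genome2 <- t2pks:::makeGenomeRecord(
    "SYNTH1", genes = genes2,
    proteins = genomeProteins(pg$genome)[genes2$gene_id],
    lengthBp = pg$genome@lengthBp)
  calls2 <- scanGenome(genome2, bank)
  expect_setequal(paste(calls2$gene_id, calls2$pks_class, calls2$subfamily),
                  paste(calls$gene_id, calls$pks_class, calls$subfamily))
})

test_that("an empty genome scans to an empty call table", {
  genome <- t2pks:::makeGenomeRecord(
    "EMPTY1", genes = data.frame(gene_id = character(0), start = integer(0),
                                 end = integer(0), strand = character(0),
                                 locus_tag = character(0),
                                 product = character(0)),
    proteins = Biostrings::AAStringSet(), lengthBp = 0)
  expect_equal(nrow(scanGenome(genome, fixtureBank())), 0)
})

test_that("novel-annotation flagging spares products naming a PKS class", {
  calls <- data.frame(gene_id = c("g1", "g2", "g3"),
                      pks_class = c("ACP", "KS", "KR"),
                      subfamily = "a",
                      product = c("hypothetical protein", "ketosynthase",
                                  NA),
                      stringsAsFactors = FALSE)
  out <- flagNovelAnnotations(NULL, calls)
  expect_setequal(out$gene_id, c("g1", "g3"))
  expect_equal(out$prior_product[out$gene_id == "g3"], "unknown")
})
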