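test_that("family generation is seeded and rate-0 reproduces the ancestor", {
  fam <- generateFamily(6, 80, 0, 0, seed = 3)
  expect_equal(unique(as.character(fam)), attr(fam, "ancestor"))
  f1 <- generateFamily(6, 80, 0.1, 0.02, seed = 4)
  f2 <- generateFamily(6, 80, 0.1, 0.02, seed = 4)
  expect_identical(as.character(f1), as.character(f2))
  f3 <- generateFamily(6, 80, 0.1, 0.02, seed = 5)
  expect_false(identical(as.character(f1), as.character(f3)))
})

test_that("mean pairwise identity decreases with the substitution rate", {
  pidAt <- function(rate) {
    fam <- generateFamily(10, 100, rate, 0, seed = 8)
    mean(pairwiseHits(fam)$percent_identity)
  }
  pids <- vapply(c(0.05, 0.1, 0.2, 0.3), pidAt, 0)
  expect_true(all(diff(pids) < 0))
})

test_that("negatives have the requested count and shuffles preserve composition", {
  neg <- generateNegatives(50, 120, seed = 12)
  expect_length(neg, 50)
  pos <- generateFamily(3, 60, 0.1, 0, seed = 13, prefix = "p")
  withShuf <- generateNegatives(2, 60, seed = 14, positives = pos)
  expect_length(withShuf, 5)
  for (i in 1:3) {
    src <- sort(strsplit(as.character(pos[[i]]), "")[[1]])
    shf <- sort(strsplit(as.character(
      withShuf[[paste0("shuf_", names(pos)[i])]]), "")[[1]])
    expect_equal(shf, src)
  }
})

test_that("negatives fall below a profile threshold almost surely", {
  fam <- generateFamily(10, 120, 0.08, 0, seed = 15, prefix = "ks")
  prof <- buildProfile(buildMsa(fam), "ks")
  neg <- generateNegatives(100, 120, seed = 16)
  sc <- scoreProfiles(prof, neg)
  above <- sum(sc$bits >= prof$threshold)
  expect_lte(above, 1) # at least 99 of 100 rejected
})

test_that("the full synthetic reference set reproduces the published layout", {
  ref <- generateReferenceSet(seed = 2)
  d <- referenceDomains(ref)
  expect_equal(nrow(d), 308)
  expect_equal(length(unique(d$gene_name)), 280)
  expect_equal(length(unique(subfamilyKey(d$pks_class, d$subfamily))), 20)
  counts <- table(d$pks_class)
  expect_equal(unname(counts[c("KS", "CLF", "ACP", "KR", "ARO", "CYC")]),
               c(43L, 43L, 44L, 30L, 67L, 57L),
               ignore_attr = TRUE)
  # didomain aromatases: each ARO a/b pair shares a gene name
  aro <- d[d$pks_class == "ARO" & d$subfamily %in% c("a", "b"), ]
  expect_true(all(table(aro$gene_name) == 2))
  # mean lengths land near the layout targets
  lay <- tableOneLayout()
  for (i in seq_len(nrow(lay))) {
    ids <- d$domain_id[d$pks_class == lay$pks_class[i] &
                         d$subfamily == lay$subfamily[i]]
    expect_equal(mean(Biostrings::width(referenceSequences(ref)[ids])),
                 lay$mean_length[i], tolerance = 0.1)
  }
})

test_that("planted genomes encode the chaining boundary in their truth", {
  ref <- fixtureChemRef()
  spec3 <- list(clusters = list(list(
    subfamilies = c("KS_a", "CLF_a", "ACP_a"), gaps = c(5000, 14999))))
  truth3 <- plantGenome(spec3, ref, seed = 6)$truth
  expect_equal(nrow(truth3), 1)
  expect_equal(truth3$n_genes, 3)
  # a 15,000 bp inter-cluster gap keeps two planted clusters distinct
  spec2 <- list(clusters = list(
    list(subfamilies = c("KS_a", "CLF_a")),
    list(subfamilies = c("KS_a", "CLF_a"))), interClusterGap = 15000)
  pg2 <- plantGenome(spec2, ref, seed = 7)
  expect_equal(nrow(pg2$truth), 2)
  gap <- pg2$truth$start[2] - pg2$truth$end[1] - 1
  expect_equal(gap, 15000)
  # truth chemotype follows the rule table for a unique combination
  specAng <- list(clusters = list(list(
    subfamilies = c("KS_a", "CLF_a", "ACP_a", "ARO_a", "ARO_b", "CYC_a"))))
  expect_equal(plantGenome(specAng, ref, seed = 8)$truth$chemotype, "Ang")
  # generation is deterministic per seed
  a <- plantGenome(specAng, ref, seed = 9)
  b <- plantGenome(specAng, ref, seed = 9)
  expect_identical(as.character(genomeProteins(a$genome)),
                   as.character(genomeProteins(b$genome)))
})
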