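test_that("multiple alignment covers all members and flags gappy columns", {
  two <- Biostrings::AAStringSet(c(a = "MKTAYIAKQR", b = "MKTAYIAKQR"))
  aln <- buildMsa(two)
  expect_equal(unique(Biostrings::width(aln)), 10)
  expect_false(any(grepl("-", as.character(aln), fixed = TRUE)))

  fam <- generateFamily(6, 80, 0.1, 0.05, seed = 31, prefix = "f")
  aln <- buildMsa(fam)
  expect_true(unique(Biostrings::width(aln)) >=
                max(Biostrings::width(fam)))
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  expect_equal(unname(attr(aln, "gapFlagged")),
               unname(colMeans(m == "-") > 0.5))
})

test_that("profile calibration admits members and rejects shuffled decoys", {
  fam <- generateFamily(8, 120, 0.08, 0.01, seed = 41, prefix = "f")
  prof <- buildProfile(buildMsa(fam), "fam")
  expect_true(all(prof$trainScores >= prof$threshold))
  shuffles <- generateNegatives(0, seed = 42, positives = rep(fam, 13)[1:100])
  sc <- scoreProfiles(prof, shuffles)
  maxDecoy <- if (nrow(sc) == 0) -Inf else max(sc$bits)
  expect_lt(maxDecoy, prof$threshold)
})

test_that("a profile of one family rejects a diverged sister family", {
  ks <- generateFamily(8, 140, 0.08, 0, seed = 51, prefix = "ks")
  clf <- generateFamily(8, 140, 0.08, 0, seed = 151, prefix = "clf")
  prof <- buildProfile(buildMsa(ks), "KS_a")
  sc <- scoreProfiles(prof, clf)
  maxOther <- if (nrow(sc) == 0) -Inf else max(sc$bits)
  expect_lt(maxOther, prof$threshold)
  expect_error(scoreProfile(prof, ""), "empty")
})

test_that("feature vectors have fixed dimensions, self-dominance and determinism", {
  fam <- generateFamily(6, 90, 0.1, 0, seed = 61, prefix = "r")
  refs <- fam
  fv <- featureVectors(fam, refs)
  expect_equal(dim(fv), c(6, 6))
  # the self-component is the maximum raw component of a reference member
  raw <- t2pks:::rawScoreMatrix(fam, refs)
  for (i in 1:6) expect_equal(unname(which.max(raw[i, ])), i)
  fv2 <- featureVectors(fam, refs)
  expect_identical(fv, fv2)
})

test_that("SVM grid search separates clean families and is deterministic", {
  fam <- generateFamily(10, 100, 0.04, 0, seed = 71, prefix = "pos")
  neg <- generateNegatives(10, 100, seed = 72)
  grid <- data.frame(C = c(1, 1, 32, 32), gamma = c(2^-7, 2^-3, 2^-7, 2^-3))
  m1 <- trainSvm(fam, neg, grid = grid, repeats = 2, seed = 5)
  expect_equal(max(m1$grid$product), 1)
  expect_equal(unname(m1$cvMetrics[c("SN", "SP")]), c(100, 100))
  m2 <- trainSvm(fam, neg, grid = grid, repeats = 2, seed = 5)
  expect_equal(c(m2$C, m2$gamma), c(m1$C, m1$gamma))
  # ties break toward the smallest C then gamma
  tied <- m1$grid[m1$grid$product == max(m1$grid$product), ]
  expect_equal(m1$C, min(tied$C))
  expect_error(trainSvm(fam[1], neg), "at least 2 positives")
})

test_that("label permutation drives the mean cross-validated MCC to chance", {
  fam <- generateFamily(20, 150, 0.1, 0.01, seed = 5, prefix = "pos")
  neg <- generateNegatives(0, seed = 6, positives = fam)
  all <- c(fam, neg); names(all) <- paste0("s", seq_along(all))
  mccs <- vapply(1:10, function(r) {
    idx <- t2pks:::withSeed(100 + r, sample(40))
    crossValidateSvm(all[idx[1:20]], all[idx[21:40]], C = 4, gamma = 2^-7,
                     repeats = 1, seed = r)$metrics[["MCC"]]
  }, 0)
  expect_lt(abs(mean(mccs)), 20)
})

test_that("cross-validation picks the protocol from the positive-set size and is reproducible", {
  fam <- generateFamily(5, 80, 0.05, 0, seed = 81, prefix = "p")
  neg <- generateNegatives(5, 80, seed = 82)
  cv <- crossValidateSvm(fam, neg, C = 4, gamma = 2^-7, repeats = 2,
                         seed = 3)
  expect_equal(cv$protocol, "LOO")
  cv2 <- crossValidateSvm(fam, neg, C = 4, gamma = 2^-7, repeats = 2,
                          seed = 3)
  expect_equal(cv$perRepeat, cv2$perRepeat)
  h <- crossValidateHmm(fam, neg, repeats = 2, seed = 3)
  expect_equal(h$protocol, "LOO")
  expect_equal(unname(h$metrics[c("SN", "SP")]), c(100, 100))
})

test_that("classification recalls members, resolves fusions and ignores decoys", {
  bank <- fixtureBank()
  ref <- fixtureChemRef()
  d <- referenceDomains(ref)
  seqs <- referenceSequences(ref)

  ks <- as.character(seqs[[d$domain_id[d$pks_class == "KS"][1]]])
  calls <- classifyProtein(ks, bank)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pks_class, "KS")
  expect_equal(calls$subfamily, "a")

  # a synthetic didomain fusion yields both constituent calls
  kr <- as.character(seqs[[d$domain_id[d$pks_class == "KR"][1]]])
  acp <- as.character(seqs[[d$domain_id[d$pks_class == "ACP"][1]]])
  fus <- classifyProtein(paste0(kr, acp), bank)
  expect_equal(nrow(fus), 2)
  expect_setequal(subfamilyKey(fus$pks_class, fus$subfamily),
                  c("KR_a", "ACP_a"))

  decoys <- generateNegatives(100, 300, seed = 99)
  expect_equal(nrow(classifyProteins(decoys, bank)), 0)

  # never more than two calls per protein, even on a triple fusion
  clf <- as.character(seqs[[d$domain_id[d$pks_class == "CLF"][1]]])
  tri <- classifyProtein(paste0(kr, acp, clf), bank)
  expect_lte(nrow(tri), 2)
})

test_that("the classifier comparison harness reports both types per subfamily", {
  layout <- data.frame(pks_class = c("KS", "CLF"), subfamily = c("a", "a"),
                       n = c(6L, 6L), mean_length = c(100, 100))
  ref <- generateReferenceSet(seed = 23, layout = layout)
  tab <- evaluateClassifiers(ref, repeats = 2, seed = 9)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("hmm_SN", "svm_SN", "winner") %in% names(tab)))
  expect_true(all(tab$protocol == "LOO"))
  expect_true(all(tab[, grep("_(SN|SP|AC)$", names(tab))] >= 0 &
                    tab[, grep("_(SN|SP|AC)$", names(tab))] <= 100))
})
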