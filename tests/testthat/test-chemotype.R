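makeCluster <- function(calls, proteins = Biostrings::AAStringSet(),
                        valid = TRUE) {
  new("PksCluster", clusterId = "c1", accession = "X",
      genes = GenomicRanges::GRanges(), proteins = proteins, calls = calls,
      valid = valid,
      chemotype = new("ChemotypePrediction", chemotype = "Unc",
                      rulePath = "unclassified", signature = character(0),
                      votes = data.frame(), ambiguous = FALSE),
      syntheticCoords = FALSE)
}

callsOf <- function(keys, geneIds = NULL) {
  kk <- t2pks:::splitSubfamilyKey(keys)
  data.frame(gene_id = geneIds %||% paste0("g", seq_along(keys)),
             pks_class = kk$pks_class, subfamily = kk$subfamily,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the embedded rule table has 11 rules with consistent uniqueness", {
  rt <- loadRuleTable()
  r <- ruleRows(rt)
  expect_equal(nrow(r), 11)
  expect_equal(countUnique(rt), 7)
  # first rule: angucyclines from both aromatase halves plus CYC a, unique
  ang <- r[r$chemotype == "Ang", ]
  expect_equal(ang$combination[[1]], c("ARO_a", "ARO_b", "CYC_a"))
  expect_true(ang$unique)
  # the Pen/Tcm shared combination is flagged non-unique under both
  shared <- vapply(r$combination, function(cc) {
    identical(cc, c("ARO_c", "CYC_a", "CYC_b"))
  }, TRUE)
  expect_setequal(r$chemotype[shared], c("Pen", "Tcm"))
  expect_false(any(r$unique[shared]))
})

test_that("overlapping pairs match the quadratic oracle and the printed pairs", {
  rt <- loadRuleTable()
  op <- overlappingPairs(rt)
  expect_equal(nrow(op), 2)
  expect_equal(op$chemotype1, c("Ant", "Pen"))
  expect_equal(op$chemotype2, c("Tet/Aur", "Tcm"))
  # O(n^2) oracle over all rule pairs
  r <- ruleRows(rt)
  keys <- vapply(r$combination, paste, "", collapse = ",")
  want <- unique(t(apply(which(outer(keys, keys, "==") &
                                 outer(r$chemotype, r$chemotype, "!="),
                               arr.ind = TRUE), 1, function(ij) {
    sort(r$chemotype[ij])
  })))
  want <- want[order(want[, 1]), , drop = FALSE]
  expect_equal(unname(as.matrix(op[, 1:2])), unname(want))
  # counting identity: unique rules plus overlapped rows cover the table
  expect_equal(countUnique(rt) + sum(!r$unique), nrow(r))
})

test_that("uniqueness flags respond to constructed tables", {
  mk <- function(chems, combos) {
    rules <- data.frame(chemotype = chems, chemotype_name = chems,
                        stringsAsFactors = FALSE)
    rules$combination <- I(lapply(combos, sort))
    rules$unique <- t2pks:::recomputeUniqueness(rules$combination, chems)
    new("RuleTable", rules = rules)
  }
  allDistinct <- mk(c("A", "B"), list(c("ARO_a"), c("CYC_a")))
  expect_equal(countUnique(allDistinct), 2)
  expect_equal(nrow(overlappingPairs(allDistinct)), 0)
  twin <- mk(c("A", "B"), list(c("ARO_a", "CYC_a"), c("ARO_a", "CYC_a")))
  expect_equal(countUnique(twin), 0)
})

test_that("signatures project ARO/CYC calls with set semantics", {
  sig <- clusterSignature(callsOf(c("KS_a", "CLF_a", "ACP_a", "ARO_a",
                                    "ARO_b", "CYC_a")))
  expect_equal(sig, c("ARO_a", "ARO_b", "CYC_a"))
  expect_equal(clusterSignature(callsOf(c("KS_a", "CLF_a"))), character(0))
  dup <- clusterSignature(callsOf(c("ARO_a", "ARO_a"), c("g1", "g2")))
  expect_equal(dup, "ARO_a")
})

test_that("the homolog vote tallies, majority-wins and reports ties", {
  ref <- fixtureChemRef()
  d <- referenceDomains(ref)
  seqs <- referenceSequences(ref)
  antId <- d$domain_id[d$pks_class == "CYC" & d$subfamily == "e" &
                         d$chemotype == "Ant"][1]
  cl <- makeCluster(
    callsOf("CYC_e", "g1"),
    proteins = Biostrings::AAStringSet(stats::setNames(
      as.character(seqs[antId]), "g1")))
  v <- homologVote(cl, ref)
  expect_equal(v$winners, "Ant")
  expect_false(v$ambiguous)
  # all collected homologs of a verbatim reference member share its lineage
  expect_equal(names(v$tally), "Ant")

  # constructed 60/40 and 50/50 splits on a synthetic reference
  fam <- generateFamily(10, 100, 0.03, 0, seed = 90, prefix = "cyce")
  mkref <- function(chems) {
    new("ReferenceSet", sequences = fam,
        domains = data.frame(domain_id = names(fam),
                             gene_name = names(fam), pks_class = "CYC",
                             subfamily = "e", source_cluster = "c",
                             chemotype = chems, stringsAsFactors = FALSE))
  }
  qcl <- makeCluster(callsOf("CYC_e", "g1"),
                     proteins = Biostrings::AAStringSet(
                       c(g1 = as.character(fam[[1]]))))
  v64 <- homologVote(qcl, mkref(rep(c("Ant", "Tet/Aur"), c(6, 4))))
  expect_equal(v64$winners, "Ant")
  expect_equal(unname(v64$tally[c("Ant", "Tet/Aur")]), c(6L, 4L))
  v55 <- homologVote(qcl, mkref(rep(c("Ant", "Tet/Aur"), c(5, 5))))
  expect_true(v55$ambiguous)
  expect_equal(v55$winners, c("Ant", "Tet/Aur"))
})

test_that("prediction follows unique rules, votes on overlaps, else unclassified", {
  rt <- loadRuleTable()
  ref <- fixtureChemRef()
  d <- referenceDomains(ref)
  seqs <- referenceSequences(ref)
  pick <- function(key, chem = NA) {
    kk <- t2pks:::splitSubfamilyKey(key)
    sel <- d$pks_class == kk$pks_class & d$subfamily == kk$subfamily
    if (!is.na(chem) && kk$pks_class %in% c("ARO", "CYC")) {
      sel <- sel & !is.na(d$chemotype) & d$chemotype == chem
    }
    as.character(seqs[[d$domain_id[sel][1]]])
  }
  mkcl <- function(keys, chem = NA) {
    prots <- Biostrings::AAStringSet(stats::setNames(
      vapply(keys, pick, "", chem = chem), paste0("g", seq_along(keys))))
    makeCluster(callsOf(keys, names(prots)), proteins = prots)
  }
  p1 <- predictChemotype(mkcl(c("KS_a", "CLF_a", "ARO_a", "ARO_b",
                                "CYC_a")), rt, ref)
  expect_equal(p1@chemotype, "Ang")
  expect_equal(p1@rulePath, "unique_match")

  p2 <- predictChemotype(mkcl(c("KS_a", "CLF_a", "ARO_c", "CYC_a",
                                "CYC_b"), chem = "Tcm"), rt, ref)
  expect_equal(p2@chemotype, "Tcm")
  expect_equal(p2@rulePath, "homolog_vote")

  p3 <- predictChemotype(mkcl(c("KS_a", "CLF_a")), rt, ref)
  expect_equal(p3@chemotype, "Unc")
  expect_equal(p3@rulePath, "unclassified")

  expect_error(predictChemotype(makeCluster(callsOf("KS_a"),
                                            valid = FALSE), rt, ref),
               "valid")
})

test_that("matching is exact-set: supersets and subsets fall to unclassified", {
  rt <- loadRuleTable()
  ref <- fixtureChemRef()
  r <- ruleRows(rt)
  allKeys <- sort(unique(unlist(r$combination)))
  ruleKeys <- vapply(r$combination, paste, "", collapse = ",")
  set.seed(17)
  for (k in 1:25) {
    sig <- sort(sample(allKeys, sample(1:5, 1)))
    cl <- makeCluster(callsOf(c("KS_a", "CLF_a", sig)))
    p <- predictChemotype(cl, rt, ref)
    inTable <- paste(sig, collapse = ",") %in% ruleKeys
    if (!inTable) {
      expect_equal(p@chemotype, "Unc", info = paste(sig, collapse = "+"))
    } else {
      expect_true(p@rulePath %in% c("unique_match", "homolog_vote"))
    }
  }
})

test_that("prediction is a pure function of the signature and homologs", {
  rt <- loadRuleTable()
  ref <- fixtureChemRef()
  keys <- c("KS_a", "CLF_a", "ARO_a", "ARO_b", "CYC_a")
  cl1 <- makeCluster(callsOf(keys))
  cl2 <- makeCluster(callsOf(rev(keys), paste0("g", 5:1)))
  expect_equal(predictChemotype(cl1, rt, ref)@chemotype,
               predictChemotype(cl2, rt, ref)@chemotype)
})
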