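test_that("local alignment reproduces the textbook instance and a DP oracle", {
  # classic BLOSUM50 / linear gap 8 instance; oracle computes 28
  expect_equal(swOracle("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
                        gapOpen = 0, gapExtend = 8), 28)
  hit <- alignLocal("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
                    gapOpen = 0, gapExtend = 8)
  expect_equal(hit$score, 28)

  set.seed(1)
  for (k in 1:12) {
    a <- paste(sample(Biostrings::AA_STANDARD[1:20], sample(10:40, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(Biostrings::AA_STANDARD[1:20], sample(10:40, 1),
                      replace = TRUE), collapse = "")
    expect_equal(alignLocal(a, b)$score, swOracle(a, b),
                 info = paste("pair", k))
  }
})

test_that("self-alignment gives 100% identity and full coverage", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  hit <- alignLocal(s, s)
  expect_equal(hit$percent_identity, 100)
  expect_equal(hit$coverage, 1.0)
})

test_that("local alignment score is invariant under argument swap", {
  a <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  b <- "MKLAYIARQRQISFVKHHFSRQEERLGLIEVNP"
  expect_equal(alignLocal(a, b)$score, alignLocal(b, a)$score)
})

test_that("empty sequences are rejected and ambiguity codes are masked", {
  expect_error(alignLocal("", "MKT"), "empty")
  # B/Z/U are masked to X, which the matrices define: no error, finite score
  hit <- alignLocal("MKTBZUAYIAKQ", "MKTXXXAYIAKQ")
  expect_true(is.finite(hit$score))
})

test_that("pairwiseHits covers all unordered pairs once", {
  fam <- generateFamily(5, 60, 0.1, 0, seed = 2, prefix = "p")
  hits <- pairwiseHits(fam)
  expect_equal(nrow(hits), choose(5, 2))
  expect_false(any(hits$query_id == hits$subject_id))
})
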