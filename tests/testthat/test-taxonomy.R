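test_that("group ratios reproduce the published per-suborder percentages", {
  expect_equal(groupRatioFromCounts(11, 6), 54.55)
  expect_equal(groupRatioFromCounts(7, 5), 71.43)
  expect_equal(groupRatioFromCounts(36, 6), 16.67)
  expect_equal(groupRatioFromCounts(7, 4), 57.14)
  expect_equal(groupRatioFromCounts(11, 2), 18.18)
  expect_equal(groupRatioFromCounts(48, 1), 2.08)
  expect_equal(groupRatioFromCounts(1, 1), 100.00)
  expect_equal(groupRatioFromCounts(5, 0), 0.00)
})

test_that("the shipped survey census recomputes all 17 printed ratios", {
  tab <- surveyTaxonCounts()
  expect_equal(nrow(tab), 17)
  printed <- c(Acidimicrobineae = 0.00, Actinomycineae = 0.00,
               Catenulisporineae = 100.00, Corynebacterineae = 0.00,
               Frankineae = 54.55, Glycomycineae = 0.00,
               Kineosporiineae = 0.00, Micrococcineae = 2.08,
               Micromonosporineae = 71.43, Propionibacterineae = 0.00,
               Pseudonocardineae = 18.18, Streptomycineae = 16.67,
               Streptosporangineae = 57.14, Bifidobacteriaceae = 0.00,
               Coriobacterineae = 0.00, Rubrobacterineae = 0.00,
               Conexibacteraceae = 0.00)
  expect_equal(stats::setNames(tab$group_ratio, tab$suborder),
               printed[tab$suborder])
})

test_that("taxon summaries bucket genomes by suborder and count valid clusters", {
  bank <- fixtureBank()
  ref <- fixtureChemRef()
  pgA <- fixturePlanted()  # Frankineae, one valid cluster
  pgB <- plantGenome(list(clusters = list(list(subfamilies = c("KS_a",
                                                               "KR_a")))),
                     ref, seed = 77, accession = "SYNTH2",
                     lineage = data.frame(
                       rank = c("order", "suborder"),
                       name = c("Actinomycetales", "Micromonosporineae")))
  resA <- mineGenome(pgA$genome, bank)
  resB <- mineGenome(pgB$genome, bank)
  tab <- taxonGroupRatio(list(pgA$genome, pgB$genome), list(resA, resB))
  expect_equal(nrow(tab), 2)
  frank <- tab[tab$suborder == "Frankineae", ]
  expect_equal(c(frank$n_sequenced, frank$n_with_pks), c(1, 1))
  expect_equal(frank$group_ratio, 100.00)
  micro <- tab[tab$suborder == "Micromonosporineae", ]
  expect_equal(c(micro$n_sequenced, micro$n_with_pks), c(1, 0))
  # conservation: total genomes with PKS equals the per-bucket sum
  expect_equal(sum(tab$n_with_pks), 1)
})

test_that("genome summaries list only PKS-containing genomes with conserved tallies", {
  bank <- fixtureBank()
  pg <- fixturePlanted()
  res <- mineGenome(pg$genome, bank)
  row <- genomeSummary(res)
  expect_equal(nrow(row), 1)
  expect_equal(row$n_type2_pks, 6)
  expect_equal(row$Ang, 1)
  codes <- c("Unc", "Ang", "Ant", "Ben", "Pen", "Tcm", "Tet/Aur")
  nValid <- sum(vapply(pksClusters(res), clusterValid, TRUE))
  expect_equal(sum(unlist(row[codes])), nValid)

  # a genome with no valid cluster is omitted
  ref <- fixtureChemRef()
  pg2 <- plantGenome(list(clusters = list(list(subfamilies = c("KS_a")))),
                     ref, seed = 5, accession = "SYNTH3")
  res2 <- mineGenome(pg2$genome, bank)
  expect_equal(nrow(genomeSummary(res2)), 0)
  expect_equal(nrow(genomeSummary(list(res, res2))), 1)
})
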