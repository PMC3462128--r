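# t2pks — genome mining of bacterial type II polyketide synthase gene clusters

Aromatic polyketides (tetracyclines, anthracyclines, angucyclines,
benzoisochromanequinones, tetracenomycins, aureolic acids, pentangular
polyphenols) are made by **type II polyketide synthases (PKSs)**:
clusters of small mono-/didomain proteins in actinobacterial genomes. The
condensing ketosynthase/chain-length-factor (KS/CLF) pair defines a
functional cluster, and the combination of aromatase (ARO) and cyclase
(CYC) subfamilies in the cluster determines the ring-folding pattern of
the product — its *chemotype*.

`t2pks` is an R package for people who mine genomes for these clusters.
It provides:

- **Subfamily clustering** — single-linkage homology clustering of a
  curated reference set (Smith-Waterman identity + coverage thresholds,
  calibrated against the labeled 20-subfamily partition of the 308
  reference domains).
- **Per-subfamily domain classifiers** — calibrated profile HMMs
  (HMMER) and RBF-kernel SVMs over normalized Smith-Waterman score
  features (libSVM), selected per subfamily by the cross-validated
  product of sensitivity and specificity; metrics
  SN = TP/(TP+FN), SP = TN/(TN+FP), AC = (TP+TN)/N and
  MCC = (TP·TN − FN·FP)/√((TP+FN)(TN+FP)(TP+FP)(TN+FN)), with 4-fold
  cross-validation for n ≥ 20 and leave-one-out below, averaged over 10
  repeats.
- **Cluster detection** — chaining of classified genes with < 15,000
  intervening bp (strict), KS+CLF validation.
- **Chemotype prediction** — an embedded rule table of 11 ARO/CYC
  combinations over six chemotypes (7 unique, 2 overlapped pairs);
  unique combinations assign directly, overlapped ones are resolved by
  the majority chemotype among reference homologs of the cluster's
  ARO/CYC domains.
- **Reporting** — GFF3 of calls and cluster spans, per-genome summary
  rows, per-suborder taxonomic group ratios.
- **Synthetic fixtures** — seeded generators for protein families,
  decoys, reference sets with the published layout, and genomes with
  planted clusters and known truth, so everything is testable offline.

## Worked example

Train a bank on the seeded fixture reference, plant a genome with a known
angucycline cluster, and mine it back:

```r
library(t2pks)

ref  <- buildChemotypeReference(seed = 7)
bank <- trainModelBank(ref, seed = 42)      # ~2 min: HMM + SVM per subfamily

spec <- list(clusters = list(list(
  subfamilies = c("KS_a", "CLF_a", "ACP_a", "ARO_a", "ARO_b", "CYC_a"))))
pg  <- plantGenome(spec, ref, seed = 301)
res <- mineGenome(pg$genome, bank)
res
#> MiningResult for SYNTH1
#>    1 clusters ( 1 valid ), 6 type II PKS proteins, 6 newly annotated

pksClusters(res)[[1]]
#> PksCluster cluster_1 on SYNTH1
#>    6 genes, 501 - 4200 bp, valid (KS+CLF)
#>    domains: KS_a CLF_a ACP_a ARO_a ARO_b CYC_a
#>    chemotype: Ang

genomeSummary(res)[, c("accession", "n_type2_pks", "Ang", "Unc")]
#>   accession n_type2_pks Ang Unc
#> 1    SYNTH1           6   1   0
```

The cluster is recovered at its planted coordinates, validated by its
KS+CLF pair, and its signature {ARO a, ARO b, CYC a} — a combination
unique to angucyclines — assigns the chemotype directly.
`writeMiningReport(res, "results/")` writes the GFF3 and TSV reports.
For real data, load a curated reference with `loadReferenceSet()` and
feed any GenBank record through `readGenBank()` (or protein FASTA
through `readProteinFasta()`, which assigns synthetic coordinates so
chaining still works). A thin CLI lives at `inst/scripts/t2pks`.

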