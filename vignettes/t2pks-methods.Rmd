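---
title: "Mining type II polyketide synthase gene clusters with t2pks"
author: "t2pks authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining type II polyketide synthase gene clusters with t2pks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bacterial aromatic polyketides — tetracyclines, anthracyclines,
angucyclines, benzoisochromanequinones, tetracenomycins, aureolic acids and
pentangular polyphenols — are assembled by type II polyketide synthases
(PKSs): small, iteratively acting mono- or didomain proteins encoded
together in a gene cluster. The condensing machinery is the heterodimeric
ketosynthase/chain length factor (KS/CLF) pair fed by an acyl carrier
protein (ACP); ketoreductase (KR), aromatase (ARO) and cyclase (CYC)
tailoring domains then fix the folding pattern of the nascent poly-β-keto
chain, and that folding pattern — the *chemotype* — is what the ARO/CYC
complement of a cluster encodes.

`t2pks` implements this mining logic end to end:

1. **Subfamily structure.** Each of the 11 type II PKS classes (KS, CLF,
   ACP, KR, ARO, CYC, KSIII, AL, AT, MCAT, TE) is partitioned into
   subfamilies by single-linkage homology clustering of the curated
   reference domains; the published reference partitions into 20
   subfamilies over 308 domains on 280 proteins.
2. **Domain classifiers.** Per subfamily, a calibrated profile HMM
   (`hmmbuild`/`hmmsearch`) and an RBF-kernel SVM over Smith-Waterman
   alignment-score features (libSVM via `e1071`), compared by
   cross-validation; tiny subfamilies fall back to best-homolog search.
3. **Cluster detection.** Classified genes are chained when fewer than
   15,000 intervening base pairs separate their gene bodies (strict
   inequality; single linkage along the genome); clusters lacking the
   KS+CLF condensing pair are flagged invalid and excluded from chemotype
   prediction and headline counts.
4. **Chemotype prediction.** A cluster's set of ARO/CYC subfamily keys is
   matched against the embedded rule table (11 combinations over six
   chemotypes: 7 unique, 2 shared pairs). A unique match assigns directly;
   a shared combination is resolved by the majority chemotype among
   reference homologs of the cluster's ARO/CYC domains; anything else is
   unclassified.

## A worked run

```{r}
library(t2pks)

ref  <- buildChemotypeReference(seed = 7)   # fixture reference set
bank <- trainModelBank(ref, seed = 42)      # HMM + SVM per subfamily

spec <- list(clusters = list(list(
  subfamilies = c("KS_a", "CLF_a", "ACP_a", "ARO_a", "ARO_b", "CYC_a"))))
pg  <- plantGenome(spec, ref, seed = 301)
res <- mineGenome(pg$genome, bank)
res
genomeSummary(res)
writeMiningReport(res, "results/")
```

For real data, load a curated reference with `loadReferenceSet()` (domain
TSV + protein FASTA), train with `trainModelBank()`, and feed any GenBank
record (`readGenBank()`) or plain protein FASTA (`readProteinFasta()`)
into `mineGenome()`.

## Model and parameter choices

**Pairwise alignment.** All sequence comparison is optimal local
(Smith-Waterman) alignment under BLOSUM62 with affine gaps (a gap of
length $k$ costs $11 + k$), via `Biostrings::pairwiseAlignment`. The
implementation is verified in the test suite against an independent
dynamic-programming oracle, including the classic BLOSUM50/linear-8
textbook instance (score 28). Ambiguity codes (B, Z, J, U, O) are kept in
stored sequences but masked to X for scoring, because the substitution
matrices define X. Homology e-values use the standard gapped
Karlin-Altschul parameters for this matrix ($\lambda = 0.267$,
$K = 0.041$); every e-value cutoff downstream is configurable, so these
constants position a dial rather than hard-code a decision.

**Subfamily clustering.** Two domains of a class share a subfamily when a
chain of pairwise hits connects them, each hit meeting a percent-identity
and a coverage threshold (coverage = aligned residues of the shorter
sequence over its length). The thresholds behind the published partition
are not part of the reference data, so `calibrateThresholds()` scans
identity 25–70% (step 5) × coverage 0.5–0.9 (step 0.1) and selects the
first pair reproducing the labeled partition exactly, falling back to the
highest Rand index. Subfamily letters are assigned by descending cluster
size, ties broken by the smallest member id. The KSIII subsplit is kept as
two potential subgroups even though no functional distinction is
established for that class.

**Profile HMMs.** Profiles are built with `hmmbuild` on a MAFFT alignment
of the members and scored with `hmmsearch --max` (the acceleration
filters are disabled: at hundreds of sequences the full dynamic
programming is cheap, and the filters otherwise hide weak cross-lineage
members of deliberately heterogeneous fixture families). The positive-call
threshold is calibrated from the minimum training-member score $s_{\min}$
as $s_{\min} - \max(10, s_{\min}/2)$. The relative term matters: in-sample
scores of small alignments are optimistic, and measured held-out members
of synthetic families score 20–40 bits below $s_{\min}$, while unrelated
and shuffled sequences score far below $s_{\min}/2$; a purely additive
10-bit margin would therefore reject genuine members without buying any
specificity.

**SVM classifiers.** A query's feature vector holds its Smith-Waterman
scores against the training sequences (positives then negatives), each
divided by that reference's self-score — an alignment-kernel
normalization that bounds components near [0, 1] and removes length bias.
The RBF grid is the conventional libSVM coarse grid ($C = 2^{-5} \ldots
2^{15}$, $\gamma = 2^{-15} \ldots 2^{3}$, powers of four), and the winning
pair maximizes the cross-validated product of sensitivity and
specificity, ties to the smaller $C$ then the smaller $\gamma$. Feature
columns are restricted to each fold's training sequences, so held-out
sequences never define feature dimensions.

**Cross-validation protocol.** Four-fold for subfamilies with at least 20
positives, leave-one-out otherwise; reported metrics average 10
repetitions (leave-one-out repetitions differ only through negative
resampling). The inner selection loops (grid search; HMM-vs-SVM choice)
use 3 repetitions — selection only needs a ranking, and the reported
evaluation re-runs the full protocol. Negatives are drawn 1:1 with the
positives: half sampled from the other type II PKS classes, half
residue-shuffled positives, all seeded.

**Combining the two classifier types.** The default `best_cv` policy uses,
per subfamily, the classifier with the higher cross-validated SN×SP
product, ties going to the HMM because its alignment envelope yields a
domain span (the SVM is sequence-global, so its implied span is the whole
protein). `union` and `intersection` policies are available. A protein
retains at most two calls — type II PKS proteins carry at most two domains
— and a call is dropped when its span overlaps an already-kept call by
more than 20% of the shorter span. Subfamilies with fewer than 5 members
(KSIII a/b, AL, MCAT, TE) use best-homolog assignment at e ≤ 1e-10.

**Chaining and validation.** The distance between two genes is the number
of intervening base pairs between their bodies
(`next.start − prev.end − 1`), and genes join a cluster when it is
strictly below 15,000 — so a 14,999 bp gap joins and a 15,000 bp gap
splits. Strand is ignored (real type II PKS clusters are bidirectional),
and origin-spanning chaining on circular genomes is not attempted. A gene
with two calls contributes both to the cluster's composition, which is
how a single didomain aromatase supplies both ARO a and ARO b.

**Chemotype rules.** Signature matching is exact set equality: Table
combinations enumerate complete ARO/CYC complements, and supersets or
subsets fall to unclassified. A `relaxed` mode (match when the signature
contains a combination; the most specific rule wins, ties go to the
homolog vote) is available for real clusters carrying extra copies. In
the homolog vote every query domain contributes *all* reference homologs
at or below the e-value cutoff (default 1e-10, configurable), not just
its best hit; exact ties are reported as ambiguous rather than broken
arbitrarily, and an overlapped signature with no homologs at all degrades
to unclassified.

## What the synthetic fixtures emulate — and what they do not

All tests run on seeded synthetic data; no download is required. Two
generators cover two incompatible regimes:

* `generateReferenceSet()` reproduces the published layout exactly —
  20 subfamilies, the printed per-class totals (e.g. ARO 67, CYC 57),
  308 domains on 280 proteins (28 didomain aromatase pairs), mean lengths
  near the printed averages. Each subfamily is one cohesive lineage
  (default substitution rate 0.08 from a random ancestor, i.e. roughly
  80–85% within-family identity, the regime of well-conserved PKS
  subfamilies), and different subfamilies are unrelated. This is the
  regime in which threshold calibration against the labeled partition is
  meaningful.
* `buildChemotypeReference()` gives each ARO/CYC subfamily one
  *independent* sub-lineage per chemotype that uses it, so the homologs
  of a query at stringent e-values are confined to its own chemotype's
  lineage and the majority vote is decidable. The two properties —
  subfamily cohesion and chemotype-resolvable sub-structure — cannot be
  realized simultaneously at this scale: sub-lineages divergent enough to
  separate votes at e ≤ 1e-10 would split their subfamily under
  single-linkage clustering. Real reference sets sit in between (homologs
  cluster by chemotype clade *within* recognizable subfamilies), which the
  synthetic world splits across the two fixtures.

Consequently, passing tests demonstrate that each mechanism is correct
under its intended regime — calibration recovers a recoverable partition;
classifiers reach 100% cross-validated accuracy on cohesive families and
chance-level MCC under label permutation; planted clusters are recovered
exactly in span, validity and chemotype — but they do not demonstrate
performance on real genomes, where family divergence, fragmented genes
and novel subfamilies all degrade the idealized picture. The generators
also make no attempt at biophysically realistic evolution: no site-rate
heterogeneity, no selection, fixed-codon reverse translation in planted
genomes.

## Problem sizes

The suite and the acceptance script run at desk scale: the full 308-domain
reference set for bookkeeping and calibration; 20-member families
(150 residues) for classifier evaluation; a 13-subfamily fixture
reference (6 members per lineage, 150 residues) behind the trained bank;
14 planted genomes of 2–10 genes covering all 11 rule rows, both sides of
the 15 kb boundary, and an invalid (CLF-less) cluster. These sizes were
chosen as the smallest at which every mechanism is exercised in a
non-degenerate way.

## Degenerate inputs and tie-breaks

Empty FASTA files warn and return an empty record; a CDS that cannot be
translated is skipped with a warning; a GenBank record with no usable CDS
is an error. Plain-FASTA input receives synthetic coordinates (1,000 bp
inter-gene spacing by default) so chaining remains exercisable, and the
synthetic-coordinate flag propagates into clusters and reports. An
all-zero confusion table is an error; a zero factor in the MCC
denominator defines MCC = 0. Cluster ordering, subfamily lettering, grid
tie-breaks and vote ties are all deterministic and documented above; every
stochastic step takes an explicit seed (default 42 for training).

## Known limitations

* Chemotype inference reaches only the carbon-chain folding pattern; no
  starter-unit, chain-length or full structure prediction.
* Nucleotide-level gene calling is out of scope: the miner consumes
  pre-called CDS features or protein FASTA.
* Classifiers depend entirely on the reference set; genuinely novel
  subfamilies or chemotype combinations are reported as unclassified
  rather than discovered.
* The external `mafft`/`hmmbuild`/`hmmsearch` binaries must be on the
  PATH.
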