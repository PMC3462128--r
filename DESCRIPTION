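Package: t2pks
Title: Genome Mining of Bacterial Type II Polyketide Synthase Gene Clusters
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identification of type II polyketide synthase (PKS) proteins,
    gene clusters and aromatic polyketide chemotypes in actinobacterial
    genomes. Partitions known type II PKS classes into subfamilies by
    single-linkage homology clustering, trains per-subfamily domain
    classifiers (profile hidden Markov models and support vector machines
    over Smith-Waterman alignment-score features), chains classified genes
    into candidate gene clusters by genomic distance, validates clusters by
    the ketosynthase/chain-length-factor criterion, and predicts the
    aromatic polyketide chemotype of each cluster from aromatase/cyclase
    subfamily combination rules with a homolog-majority fallback. Includes
    seeded generators for synthetic protein families, decoy sequences and
    genomes with planted clusters, so the whole pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    e1071,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
SystemRequirements: HMMER (>= 3.1, hmmbuild and hmmsearch on the PATH),
    MAFFT (mafft on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'align.R'
    'metrics.R'
    'cluster.R'
    'hmm.R'
    'hmmcv.R'
    'svm.R'
    'bank.R'
    'classify.R'
    'chemotype.R'
    'mining.R'
    'taxonomy.R'
    'synthetic.R'
    'io.R'
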