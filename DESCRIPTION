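Package: scSubclone
Title: Subclone Analysis of Single-Cell Tumor Transcriptomes with
    Expressed-SNV Genotyping and Prognostic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting intra-tumoral heterogeneity from
    single-cell RNA-seq: permutation saturation statistics comparing
    pooled single cells with bulk profiles, a variant filter cascade
    that reduces RNA-seq calls to tumor-specific expressed SNVs,
    per-cell trinary genotyping under allelic dropout, droplet digital
    PCR Poisson quantification, a univariate-Cox prognostic risk score
    with percentile-cutoff classification, deterministic assignment of
    cells to genotype-by-risk subgroups, and SVM classification of
    drug-surviving bulk populations against single-cell subgroup
    signatures. A synthetic-data generator with planted subclones,
    variant artifacts and survival cohorts makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    e1071,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
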