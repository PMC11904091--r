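Package: triosplice
Title: Inheritance-Aware Reanalysis of Trio Exome Variants with Gene
    Constraint and Intron-Inclusive Splice Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A stepwise reanalysis strategy for trio whole-exome sequencing
    data from probands with congenital anomalies. Variants are classified by
    trio inheritance pattern (de novo, inherited heterozygous, recessive
    homozygous, X hemizygous, compound heterozygous), gated on gene
    constraint (LOEUF, loss-of-function observed/expected upper bound
    fraction), and screened for splicing impact in exons, canonical splice
    sites, and near-exon intronic windows using SpliceAI-style delta scores,
    Pangolin scores, and maximum-entropy splice-motif score changes. The
    package orchestrates the initial exon/splice-site analysis and three
    reanalysis steps (constraint prioritization, phenotype-driven gene-panel
    screening, and constrained genome-wide intronic screening), accounts
    cohort-level diagnostic yield, compares LOEUF distributions across
    inheritance-mode categories with Welch's t test, and ships a synthetic
    trio-cohort generator with planted variants and a truth table for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
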