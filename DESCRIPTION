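Package: dnmtrio
Title: De Novo Mutation Discovery, Phasing and Classification in Sequenced Trio Cohorts
Version: 0.1.0
Authors@R: person("dnmtrio", "developers", role = c("aut", "cre"), email = "dnmtrio@example.org")
Description: Tools for inferring de novo mutations (DNMs) in parent-child
    trios from multi-platform sequencing evidence. Implements candidate
    selection from trio genotypes, a tri-platform (PacBio HiFi, Oxford
    Nanopore, Illumina) read-validation cascade with cluster, recurrence,
    allele-balance and homopolymer filters, read-backed parent-of-origin
    phasing via distance-weighted informative-SNP inheritance scores,
    germline versus postzygotic classification combining per-haplotype read
    composition with allele-balance concordance and pooled binomial tests,
    callable-genome and region-stratified mutation-rate estimation with
    exact Poisson intervals, and mutation-spectrum, clustering and
    parental-age statistics. Ships a synthetic trio-cohort generator that
    emulates the read evidence these analyses assume, so the whole pipeline
    is testable without access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    BiocGenerics,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation,
    withr
Config/testthat/edition: 3
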