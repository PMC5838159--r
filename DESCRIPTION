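Package: cnvmix
Title: Multi-Sample Copy Number Variation Calling from Read Depth and
    Mate-Pair Insert Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint calling of copy number variants (CNVs) across multiple
    sequenced samples. Per genomic segment, read counts and the number of
    spanning mate pairs with aberrant insert sizes are modelled by a
    Bayesian mixture over digitized copy-number states (a Poisson emission
    for depth and a Binomial emission for insert-size aberration counts),
    fitted by maximum a posteriori expectation-maximization with Dirichlet
    and Beta priors. Includes alignment ingestion from BAM files, a seeded
    summary-level simulator of multi-sample CNV datasets with ground
    truth, per-state precision/recall evaluation, and hierarchical
    clustering of samples by their CNV genotype matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
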