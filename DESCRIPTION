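Package: rpls
Title: Gene-Based Association Testing of Rare and Common Variants via a
    Partial Least Squares Supervariant
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-step gene-based association testing for sequencing
    studies of unrelated individuals. Within each gene, variants are first
    screened by an elastic-net regression; the selected variants are then
    combined into a single supervariant by the first partial least squares
    component, and the supervariant coefficient is tested in a generalized
    linear model with covariate adjustment (the rPLS test). The package
    also provides the SUM burden test, the sequence kernel association
    test (SKAT) and its optimal burden/variance-component combination
    (SKAT-O) for comparison, a replicate-based phenotype simulator with a
    rare-skewed allele-frequency spectrum, and an evaluation harness
    computing power, type-I error, and accuracy over simulation
    replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    glmnet,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
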