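Package: genedup
Title: Census, Ancient-Origin Dating, and Selection Analysis of Duplicated
    Genes in Multi-Replicon Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies duplicate gene pairs in a bacterial genome by
    reciprocal protein similarity with an exact affine-gap global alignment
    kernel, classifies their functional (COG) distribution with chi-square
    goodness-of-fit tests, dates each duplication relative to speciation by
    maximum-likelihood quartet topology (WAG model, Felsenstein pruning,
    nonparametric bootstrap), estimates synonymous and nonsynonymous
    substitution rates per pair (Nei-Gojobori counting and a kappa- and
    frequency-corrected approximate method), compares duplicate retention
    across related strains, and overlaps duplications with
    horizontal-gene-transfer intervals. Includes a codon-model genome
    simulator with known duplication history for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
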