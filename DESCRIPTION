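Package: stressmeth
Title: Genome-Wide Salivary Methylation and Expression Analysis of
    Childhood Stress Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline linking a continuous childhood-stress
    exposure score to salivary DNA methylation and gene expression.
    Implements 450k-style probe filtering and beta-to-M conversion,
    per-CpG linear models with empirical-Bayes variance moderation, a
    two-state hidden-Markov local-index-of-significance (LIS/aLIS) false
    discovery rate procedure over position-ordered z-scores, permutation
    enrichment of differentially methylated loci across genic structures,
    CpG-island relations and chromosomes, quantile-normalized
    differential expression against the same exposure score,
    methylation-expression-gene-list integration with Yates-corrected
    chi-square enrichment, and a discriminative k-mer motif check on DML
    flanking sequence. Ships a synthetic-data module that generates a
    miniature genome, probe manifest and matched methylation/expression
    matrices with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
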