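Package: evotrace
Title: Planted-Truth Resequencing and Phenotypic Convergence Analysis for
    Bacterial Laboratory Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse genotypic and phenotypic change in bacterial
    laboratory-evolution experiments, driven by a synthetic-data generator
    that plants known mutations as ground truth. Implements dual-platform
    point-mutation and small-indel calling with explicit depth, allele-ratio
    and binomial-tail filters; a mate-pair distance-deviation scan for large
    indels with insertion-sequence (IS) classification from counterpart
    reads; read-depth duplication detection; mutation-fixation timelines
    from population allele frequencies; specific growth-rate estimation from
    OD600 series with many-to-one Dunnett comparisons; and transcriptome and
    metabolome convergence analysis (quantile normalisation, quantification
    limit filtering, log-ratios, PCA trajectory orbits, pairwise strain
    correlations). All inputs and outputs are plain tibbles so pipelines
    compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Biostrings,
    limma,
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
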