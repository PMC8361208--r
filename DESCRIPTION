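Package: phageome
Title: Gut Phageome Quantification and Comparative Analysis from Read Recruitment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the human gut phageome from per-sample read-to-contig
    alignments and compares it across clinical groups. Implements
    identity/length alignment filtering, coverage-based chimera and length
    filters, RPKM abundance matrices, greedy 95%-identity sequence clustering
    with subsample-based richness estimation, MEGAN-style hit filtering and
    lowest-common-ancestor taxonomy with prokaryotic/eukaryotic rollup,
    rarefaction-based alpha diversity, Bray-Curtis and Aitchison beta
    diversity with ordination and permutation tests, core/common/individual
    prevalence classes, group-unique contig sweeps, prevalence-shift analysis,
    negative-binomial differential abundance with median-of-ratios
    normalization, and Spearman correlation screens against bacterial taxa and
    clinical covariates. Ships a synthetic-data generator with planted ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rcpp,
    ape,
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
    utils,
    vegan,
    withr
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
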