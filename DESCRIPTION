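Package: concordare
Title: Genotype Concordance and Reproducibility Metrics for Sequencing Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analytical validation of whole-exome and
    whole-genome sequencing callsets. Normalizes variant callsets
    (multi-allelic decomposition, parsimony and indel left-alignment),
    joins callsets under strict variant equality, and computes genotype
    concordance, non-reference sensitivity (NRS), non-reference genotype
    concordance (NRC) and precision. Computes callable regions from
    per-base depth and MAPQ0 fractions, coverage summaries over target
    intervals, precision-recall curves over variant-quality thresholds,
    site-level evaluation against validated gene-panel truth sets,
    replicate call-uniformity tables, and regression of pairwise
    concordance on replicate comparison kinds. Includes deterministic
    synthetic-data generators (truth callsets, genotype-confusion
    corruption, quality-score mixtures, coverage tracks, replicate
    families with batch effects) so the whole pipeline can be exercised
    and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
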