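Package: probdnf
Title: proBDNF/totBDNF Stress Biomarker Analysis for Teleost Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying biological stress in fish from Western-blot
    densitometry of brain-derived neurotrophic factor (BDNF). Implements the
    proBDNF/(proBDNF+matBDNF) stress score, mean-plus-1SD threshold
    classification, and diagnostic test performance (sensitivity, specificity,
    predictive values), together with utilities for multi-5'UTR-exon BDNF gene
    models (GT-AG splice validation, bipartite transcript assembly, upstream
    in-frame ATG and CRE motif scanning), BDNF precursor processing (furin and
    SKI-1 cleavage motifs, N-glycosylation sequons, molecular weight), and
    semiquantitative RT-PCR analysis of transcript-variant regulation. A
    synthetic-data module generates densitometry cohorts, expression panels
    and test loci with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
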