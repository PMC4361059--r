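Package: mutmosaic
Title: Somatic Mutation Calling and Cross-Lesion Heterogeneity for Paired
    Tumor-Normal Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing somatic single-nucleotide variants across
    multiple synchronous lesions sampled from the same patient. Implements a
    paired tumor/normal genotype caller with a depth, strand-bias and
    mapability filter cascade, a minimum-evidence subclonal caller operating
    on read-level evidence with repeat, known-variant and read-end
    exclusions, a deep-amplicon validation decision rule, mutational-index
    and substitution-spectrum/CpG-context metrics with an inverse (noise
    floor) analysis, and per-patient cross-lesion overlap, clonality and
    gene multi-hit reports. A synthetic cohort generator produces paired
    exome-like strand-aware read counts with clonal and subclonal somatic
    mutations, germline variants, sequencing error and alignment artifacts
    so that the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
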