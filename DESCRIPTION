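Package: cfdnatools
Title: Joint Nucleosome Footprinting and Methylation Profiling of Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of cell-free DNA (cfDNA) sequencing data
    that carries both fragmentation and cytosine-conversion information.
    Computes per-position windowed protection scores (WPS) from aligned
    fragment intervals, calls nucleosome peaks and interpeak distances,
    quantifies nucleosome positioning strength around transcription start
    sites as a function of gene expression, summarizes per-cytosine
    methylation calls over target loci, deconvolves sample methylomes into
    reference tissue fractions by constrained least squares, and estimates
    the donor-derived cfDNA fraction in transplant recipients from
    donor-specific alleles. A synthetic-data layer generates
    nucleosome-phased fragments, binomially sampled methylation mixtures and
    allele pileups so that every stage is testable without sequencing data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
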