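Package: crispant
Title: Quantify Mosaic CRISPR-Cas9 Mutagenesis in F0 Animals from
    Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for genotyping mosaic F0 ("crispant") animals from
    CRISPR-Cas9 amplicon deep sequencing.  Reads are aligned to amplicon
    references, insertion/deletion events in a window around each
    predicted sgRNA cleavage site are called and classified as
    frameshift, in-frame or non-coding, and per-animal allele fractions
    are converted into the probability that every allele of a diploid
    animal carries at least one (frameshift) mutation, for single sgRNAs
    and pooled sgRNA panels.  Also profiles sgRNA-specific indel spectra
    across cohorts, computes a normalized head-size ("microcephaly")
    index from morphometric measurements, and simulates mosaic cohorts
    with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
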