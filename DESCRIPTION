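Package: bindosage
Title: Bin-Based Chromosomal Dosage Analysis for CNV Detection in Polyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects large copy-number variations (deletions and insertions
    of hundreds of kilobases to several megabases) from low-coverage
    whole-genome sequencing of polyploid genomes. Aligned read placements are
    counted in fixed-size genomic bins, converted to relative sequence read
    coverage (RSRC) against a control sample so the control sits at the
    ploidy, and discretized into integer dosage states; runs of at least
    three consecutive deviating bins are called as CNV events, optionally
    filtered by concordance across clonal biological replicates to remove
    endoreplication-like artifacts. Includes gene-overlap annotation of
    called events, qPCR relative copy-number arithmetic for wet-lab
    validation, a synthetic read-placement generator with known ground truth
    for end-to-end benchmarking, and RSRC plotting. Developed around triploid
    banana (Musa acuminata) mutation-breeding screens but applicable to any
    organism with a chromosome-level assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
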