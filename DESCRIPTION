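Package: plasmacnv
Title: Copy-Number Profiling of Tumor DNA in Plasma from Shallow
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects somatic copy-number aberrations and aneuploidy from
    shallow (~0.1x) whole-genome sequencing of cell-free plasma DNA.
    Builds equal-mappability genomic windows over a PAR-masked reference,
    counts aligned reads per window, corrects GC bias with LOWESS,
    normalizes against a healthy-control cohort, segments log2 ratio
    profiles with circular binary segmentation, and scores samples with a
    battery of z-score statistics (per-window, segmental, gene-region and
    genome-wide) with leave-one-out cross-validation of controls.
    Includes an in-silico dilution simulator for detection-limit (ROC)
    analysis, a split-read module that maps rearrangement breakpoints at
    base-pair resolution in fragmented cfDNA reads, and a synthetic
    fixture generator producing reference genomes, control cohorts and
    tumor-like samples for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    Rsamtools,
    Rcpp,
    jsonlite,
    ape,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
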