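Package: refbias
Title: Measuring, Visualizing and Diagnosing Reference Bias in Diploid
    Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies reference bias at heterozygous sites of a diploid
    donor from short-read alignments. Computes simulation, mapping and
    assignment allelic balance (SB/MB/AB), assigns reads to haplotypes with
    a naive pileup-trusting method or a tandem-repeat-aware context-matching
    method, categorizes bias events (loss, flux, local, outlier) from the
    normalized-balance plane, ranks likely-biased sites on real data from
    allelic balance and mean mapping quality, and scans pileups for biased
    regions with sliding-window read-depth, variant-density and
    non-diploidy Z-scores. Includes a diploid read simulator with truth
    tags, a truth-preserving oracle aligner and controllable bias injection
    so the whole workflow is testable end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    vcfR,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
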