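Package: refstab
Title: Reference-Gene Stability Screening, Ranking and qPCR Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting and validating housekeeping (reference) genes
    for qRT-PCR normalization. Screens transcriptome-wide FPKM matrices for
    housekeeping-like candidates (mean expression, coefficient of variation,
    maximum fold change and a dispersion measure, combined by thresholded
    intersection), re-implements four quantification-cycle (Ct) based
    stability algorithms (geNorm, NormFinder, BestKeeper and the pairwise
    delta-Ct method), aggregates them with a min-max standardized composite
    score (ComprFinder) and a geometric-mean-of-ranks comparator
    (RefFinder-style), and provides multi-gene normalization factors,
    2^-deltaCt relative expression, paired stage tests, normalization-scheme
    correlation, dilution-series amplification efficiency, and seeded
    simulators of Ct and FPKM data with planted stability structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
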