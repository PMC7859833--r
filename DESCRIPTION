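Package: ribocontrast
Title: Two-Contrast Ribosome Profiling Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating genes responsive to an unconditioned stimulus
    alone from genes responsive to associative contextual fear conditioning in
    paired ribosome-profiling / total-mRNA experiments. Implements RPKM and
    translational-efficiency quantification, footprint quality control (length,
    reading frame, P-site offsets, metagene periodicity), replicate correlation,
    PCA and complete-linkage clustering, fold-change differential calling with
    contrast set subtraction, 5'/3' UTR feature and motif characterization
    (uORF, TOP, configurable motif registry) with a simplified base-pairing
    minimum-free-energy model, and analytics for validation assays (polysome
    trace polysome/monosome ratios, heavy/light polysome qPCR with spike-in
    normalization, delta-delta-Ct fold changes, freezing scores). A seeded
    synthetic-data module with planted ground truth makes every stage testable
    without animal-derived sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    limma,
    pracma,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
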