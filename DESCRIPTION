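Package: sccgh
Title: Single-Cell BAC Array CGH Simulation and Cell-Cycle-Aware Imbalance Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how DNA replication in S phase compromises the
    detection of segmental chromosomal imbalances by single-cell BAC array
    comparative genomic hybridization (aCGH), the platform used in
    preimplantation genetic diagnosis. Provides a mechanistic simulator of
    single-cell two-channel array intensities (stochastic origin firing
    organised in replication-timing domains, whole-genome-amplification and
    hybridization noise), signal-to-noise filtering and ratio-of-means
    normalization, a threshold-and-run segmental caller (log2 ratio +/-0.3,
    at least half of the region probes, a minimum run of 10 consecutive
    probes), cell-cycle phase attribution from replication-domain
    oscillation, and rank-sum / chi-square group comparisons, together with
    a packaged per-cell probe-count table for three carrier cell lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
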