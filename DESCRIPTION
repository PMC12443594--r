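Package: esctools
Title: Detection, Quantification and Interpretation of Excised Signal
    Circles from V(D)J Recombination
Version: 0.1.0
Authors@R:
    person("esctools", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational machinery for studying excised signal circles
    (ESCs), the circular DNA by-products of deletional V(D)J recombination.
    Provides a toy immunoglobulin locus model with enumerated junction
    reference databases, simulators for clonal populations carrying ESCs
    under replication/dilution/segregation dynamics and for LAM amplicon
    and WGS-style paired-end reads, a divergent-read signal-joint detector
    with split-read refinement, a LAM junction calling pipeline
    (demultiplex, pair merge, seeded local alignment, normalization and
    thresholding), replication and persistence inference (dilution
    predictions, observed/predicted ratios, clonotype extraction, major
    event detection), a cryptic-RSS scanner with structural-variant
    mechanism classification, and exact small-sample statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
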