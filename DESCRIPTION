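Package: forktrap
Title: Replication Dynamics and Marker Frequency Analysis for Multi-Origin
    Bacterial Chromosomes
Version: 0.9.0
Authors@R:
    person("forktrap", "developers", email = "forktrap@example.org",
           role = c("aut", "cre"))
Description: Models DNA replication of circular bacterial chromosomes carrying
    arbitrary combinations of active origins and polar replication fork traps
    (ter/Tus), and predicts the marker-frequency (sequencing read-depth)
    profiles of exponentially growing populations. Implements the downstream
    marker frequency analysis pipeline: normalisation of binned read counts
    against a stationary-phase control, circular tricube degree-2 LOESS
    smoothing with periodic boundaries, and profile feature calling (low
    points, origin peaks, ter-associated steps). Provides inversion and tandem
    duplication operators with profile-continuity scoring to identify gross
    chromosomal rearrangements from read depth, non-negative least-squares
    deconvolution of subpopulation origin usage, and a synthetic-data generator
    so every analysis is reproducible without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
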