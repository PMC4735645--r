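Package: lpcnet
Title: Lagged Phase Coherence Networks from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for resting-state EEG functional
    connectivity. Builds band-wise lagged phase coherence networks from
    multichannel recordings, estimates the 1/f spectral exponent, computes
    weighted graph-topology metrics (node strength, clustering coefficient,
    local efficiency, Dijkstra functional distances, characteristic path
    length), relates connectivity to physical electrode distance, correlates
    shortest-path structure across frequency bands, and compares two groups
    with Fisher r-to-z maps, regression-slope contrasts and a mixed
    repeated-measures ANOVA. Includes a seeded multichannel simulator with
    1/f^alpha background noise and planted band-limited lagged couplings so
    every stage can be validated against a known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
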