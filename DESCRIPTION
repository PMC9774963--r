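Package: beaktraj
Title: Life-History Reconstruction from Stable-Isotope Trajectories in
    Cephalopod Beaks
Version: 0.9.0
Authors@R:
    person("beaktraj", "developers", email = "beaktraj@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct the life history of squid from ontogenetic
    stable-isotope trajectories (d13C, d15N) measured along sequential
    subsections of the upper beak crest.  Includes power-law beak allometry
    (crest length to mantle length to body mass), trophic-level estimation
    with a beak-tissue correction and an Arctic trophic enrichment factor,
    an individual specialization index, rank-based tests for incomplete
    repeated measures (Skillings-Mack with Nemenyi post hoc), isotopic-niche
    metrics (standard ellipse areas, convex hulls, probabilistic niche-region
    overlap), a Bayesian stable-isotope diet mixing model with
    mixing-polygon feasibility screening, an ecological life-stage
    classifier, and a synthetic-data generator so the whole pipeline is
    testable without the original measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
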