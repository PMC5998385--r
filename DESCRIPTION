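Package: atriafit
Title: Locally Personalised Left-Atrium Electrophysiology Models from
    Multi-Electrode Catheter Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates locally personalised models of left-atrial
    electrophysiology from multi-electrode (PentaRay-style) catheter
    recordings. Estimates local activation times, conduction-velocity
    restitution and effective refractory periods from bipolar electrograms;
    fits a modified Mitchell-Schaeffer cell model per electrode against a
    pre-computed restitution database built with a 1D monodomain cable
    simulator; extrapolates parameters over a triangulated surface by
    nearest-neighbour mapping; simulates S1S2 pacing with an isotropic
    monodomain model on the surface; localises the effective stimulus with a
    graph-eikonal search; and scores predictions with regression, Pearson
    correlation, covariance slender-ratio and functional-block indices. A
    synthetic-data module generates ground-truth cases so the whole pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
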