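Package: cytotraits
Title: Individual-Level Functional Trait Analysis from Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts per-event flow-cytometry optical measurements into
    individual-level functional traits for phytoplankton, and characterises
    the resulting trait space. Provides density-based gating of the target
    population (hierarchical density clustering of log-transformed optical
    channels), derivation of eight functional traits from scatter and pigment
    fluorescence channels, collinearity pruning and z-standardisation, an
    integrated phenotype via principal component analysis with a permutation
    test for axis significance, Gaussian kernel-density hypervolumes with
    functional richness, evenness and dispersion indices and hypervolume
    Jaccard overlap, rank-based treatment comparisons (Kruskal-Wallis with
    Conover-Iman post hoc tests), nutrient-limitation bioassay calls, and
    projection of natural-community samples onto laboratory-derived treatment
    fingerprints along a nitrogen:light gradient. A synthetic-data module
    generates event tables, bead calibrations, field series and bioassay
    readings with the statistical structure the analysis assumes, so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
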