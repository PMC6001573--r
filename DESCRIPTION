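Package: gliaquant
Title: Quantitative Analysis of Microglial Motility, Membrane Currents and
    Amyloid-Beta Clearance
Version: 0.1.0
Authors@R:
    person("Anna", "Keller", email = "anna.keller@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify microglial behaviour across the assays used to
    characterise neurotrophin-modulated microglia. Covers time-lapse imaging
    (segmentation, tracking, cell speed, the membrane-dynamics statistic
    dA/p, and roundish/polarized shape-state morphing), whole-cell
    voltage-clamp analysis (step-protocol I/V curves, difference currents and
    reversal potentials, miniature EPSC detection with noise-scaled amplitude
    and area thresholds, series-resistance quality control), accounting of
    internalized amyloid-beta over washout time courses (degradation deltas
    and supernatant release), and matrix-level assay statistics
    (background-flag filtering, upper-quartile normalization, fold-change and
    moderated-t feature selection, principal component analysis, and the
    standard group-comparison tests). Every pipeline stage is paired with a
    synthetic-data generator that plants known ground truth, so the whole
    analysis chain is testable without any external data.
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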