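Package: retinaquant
Title: Quantification Pipeline for Zebrafish Retinal Regeneration Studies
Version: 0.1.0
Authors@R: person("Retina", "Quant", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated quantification machinery for zebrafish retinal
    regeneration experiments: two-channel nuclear colocalization counting in
    confocal cryosection images (threshold ensemble of Otsu, multi-Otsu and
    local mean; connected-component area filtering; binary-AND overlay;
    counts normalized to region-of-interest area or curvilinear distance),
    manual-rule marker scoring, delta-delta-Ct qPCR fold-change analysis with
    reference-gene suitability screening and non-detect handling, and the
    accompanying nonparametric group statistics (Welch tests, Kruskal-Wallis
    with tie correction, Conover-Iman post hoc). A synthetic-data module
    generates confocal-like retinal sections with exact ground truth and qPCR
    Ct tables with programmed effects, so the full pipeline is testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
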