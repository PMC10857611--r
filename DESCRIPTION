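Package: brachyMC
Title: Monte Carlo Dosimetry of HDR 192-Ir Brachytherapy Sources
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analog Monte Carlo photon transport and simplified
    condensed-history electron transport through constructive solid geometry
    models of the microSelectron mHDR-v2 and mHDR-v2r high-dose-rate 192-Ir
    brachytherapy sources.  Scores absorbed dose on spherical (r, theta)
    tally grids in a 40 cm water sphere and air kerma in thin air shells in
    vacuo, and derives the TG-43U1 brachytherapy dosimetry dataset: air kerma
    strength, dose-rate constant, radial dose function and 2D anisotropy
    function, together with a type A/B uncertainty budget.  Ships static
    photon cross-section and electron stopping-power tables and the 192-Ir
    photon and electron emission spectra as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    tools,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
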