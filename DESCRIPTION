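Package: cytodose
Title: Cytogenetic Biological Dosimetry from Telomere- and
    Centromere-Stained Aberration Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for radiation biodosimetry based on unstable
    chromosomal aberrations scored after telomere and centromere
    staining. Ingests per-metaphase or per-dose score tables, applies
    the 46-centromere completeness filter, converts aberration classes
    to double-strand-break (DSB) counts with fixed per-class weights,
    calibrates linear-quadratic dose-response curves by quasi-Poisson
    maximum likelihood with cells scored as exposure, computes Papworth
    u dispersion diagnostics and exact (Garwood) Poisson confidence
    intervals, inverts calibration curves to absorbed-dose estimates
    with Merkle uncertainty bounds, compares donor groups by exact
    conditional rate tests, Kruskal-Wallis tests and Wald curve
    contrasts, and simulates synthetic metaphase score tables with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
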