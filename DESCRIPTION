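Package: iontrack
Title: Monte Carlo Ion Track Structure and Microdosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-interaction Monte Carlo transport of therapeutic ions
    (protons to carbon and oxygen) with screened Rutherford elastic
    scattering, Bethe stopping power with Bohr energy-loss straggling, and a
    simplified delta-electron model. Scores projected-angle multiple
    scattering distributions (with Gaussian-core fits and Highland's
    analytic width), radial dose profiles of ion tracks, depth-dose curves,
    and lineal-energy microdosimetric spectra in micrometer
    tissue-equivalent sites, plus Poisson fluence-to-hit statistics for
    cell-traversal experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
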