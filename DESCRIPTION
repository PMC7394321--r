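Package: virospectra
Title: Joint Estimation of Viral Richness and Average Genome Length from
    Contig Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Database-free estimation of the ecological parameters of a
    metavirome from its contig spectrum alone. Fits an extended
    Lander-Waterman model of contig formation to the observed spectrum and
    jointly estimates viral richness, the community-average genome length,
    the rank-abundance law (power-law, exponential, logarithmic or
    lognormal) and its shape parameter by variance-weighted least squares,
    minimised with a niched genetic algorithm over abundance-model and
    genome-length subspaces followed by iterative grid refinement. Includes
    a population and contig-spectrum simulator (fixed and normally varying
    genome lengths), benchmark metrics (signed relative error, CV(RMSE)),
    plain-text spectrum file I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
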