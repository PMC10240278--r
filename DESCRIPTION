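Package: zonalipid
Title: Zone-Resolved Hepatic Lipid Signatures from Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of desorption electrospray ionisation
    mass spectrometry imaging (DESI-MSI) data over the liver lobule. Provides
    a synthetic lobule generator with known zonal lipid effects, spectral
    preprocessing (smoothing, baseline correction, peak picking, cross-pixel
    alignment, total-ion-count normalisation), accurate-mass lipid annotation
    with adduct and isotope-pattern rules, region-of-interest sampling across
    the periportal/midzone/pericentral axis, per-lipid mixed-model tests of
    zonation with Benjamini-Hochberg control, and pathway ranking by relative
    betweenness centrality with hypergeometric over-representation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
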