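Package: optopore
Title: Membrane Resealing Kinetics and Macromolecule Loading in
    Nanoparticle-Mediated Photoporation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gold-nanoparticle mediated photoporation of
    mammalian cells. Extracts membrane resealing times from voltage-sensitive
    dye fluorescence time series (linear photobleaching correction, dip
    detection, 90 percent recovery rule), simulates macromolecule loading
    through transient membrane pores with a Brownian-motion Monte Carlo model
    whose step size follows Stokes-Einstein molecular-weight scaling, fits the
    exponential calibration relations linking laser fluence, resealing time,
    molecular weight and loading efficiency, and generates fully synthetic
    image stacks and trace sets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
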