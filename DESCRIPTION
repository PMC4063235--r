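Package: epicar
Title: Exceedance-Probability Disease Cluster Screening with a Zero-Inflated
    Poisson Intrinsic CAR Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: First-step geographic disease cluster investigation on a square
    kilometre pixel grid. Geocoded point health records (e.g. birth records
    flagged for very low birth weight) are projected to planar kilometre
    coordinates, binned into 1 km^2 pixels, and windowed around putative
    toxic sources. A zero-inflated Poisson model with an intrinsic
    conditional autoregressive (ICAR) spatial prior is fitted by Markov
    chain Monte Carlo; the per-pixel posterior exceedance probability that
    the relative risk exceeds one is mapped, and clusters are screened as
    connected components of high-exceedance pixels. Includes a synthetic
    birth-record generator with known distance-decay risk for validation,
    convergence diagnostics, and prior/outcome sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    geosphere,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
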