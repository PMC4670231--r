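Package: grayK
Title: Grayscale Ripley's K-Function for Quantifying Aggregation in Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extends Ripley's K-function to 2-D grayscale images in which
    pixel intensity is interpreted as a particle count, allowing overlapping
    events at very high densities. Implements the full-field Besag edge
    correction that restores centering of the normalized statistic K-tilde
    at high densities and small radii, Monte-Carlo reference distributions
    under complete spatial randomness with empirical and Cornish-Fisher
    critical quantiles, synthetic image generators (CSR fields, circular
    clusters with controlled aggregate-to-diffuse and signal-to-background
    ratios, confocal-style point-spread-function blur and Poisson noise,
    decimated study regions), and segmentation-based characterization of
    aggregates (granulometry, maximum-entropy thresholding, rolling-ball
    background subtraction, three-class Otsu masking, truth/estimate
    similarity indices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
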