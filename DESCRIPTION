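Package: sadscale
Title: Scaling and Forecasting of Species Abundance Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how species abundance distributions (SADs) change
    with sample size. Provides log2 (octave) binning, raw/central/standardized
    moments and skewness of abundance vectors, spatially ordered accumulation
    of field transects, power-law fitting of the raw moments against sample
    size, and forecasting of the SAD to larger sample sizes by reconstructing
    the abundance-class histogram from extrapolated moments with scaled
    discrete Tchebichef polynomials. Includes a spatially explicit zero-sum
    neutral community simulator with configurable dispersal kernels, used to
    generate test communities contrasting high and low dispersal ability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
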