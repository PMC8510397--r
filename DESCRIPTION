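Package: codafood
Title: Compositional Data Analysis for Chemical Element Profiles in Food
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Log-ratio analysis of chemical element concentration tables
    (samples by parts, mg/kg) as used in food authentication and
    adulteration screening. Provides the closure operation and the centred
    (clr) and pivot isometric (ilr) log-ratio representations with their
    inverses, replacement of non-detects below the detection limit by
    constant, two-thirds-detection-limit, uniform and iterative
    censored-PLS strategies, principal component analysis with biplot
    layouts over compositional and non-compositional pre-processing
    regimes, a repeated stratified cross-validation benchmark of linear
    discriminant analysis, k-nearest neighbours and a dense feed-forward
    neural network over the replacement x representation grid, and a
    logistic-normal synthetic data generator with adulteration and
    left-censoring so the whole pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    class,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
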