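Package: walkerkinetics
Title: Stepping Kinetics of Confined DNA Walkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic theory of cartwheeling DNA-walker stepping kinetics
    under soft steric confinement. Provides the confined free-end probability
    densities of a walker-foothold complex (hemispherical-shell baseline,
    sine-series slit confinement for tailed footholds, cosine confinement for
    origami trenches, and their combination), their reduction to an effective
    radial potential about a binding target, mean first-passage stepping times
    via the Szabo relation with a partially reactive contact boundary, and the
    resulting stepping-rate enhancements over tether-target distance. Includes
    a synthetic free-end point-cloud generator, parameter fitting against
    point-cloud marginals, a minimal annulus fit, an independent
    Brownian-dynamics first-passage oracle, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
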