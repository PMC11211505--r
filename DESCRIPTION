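Package: stmmr
Title: Bayesian Spatio-Temporal CAR Models for Areal Maternal Mortality Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits Bayesian spatio-temporal random-effects models for panels of
    areal maternal mortality ratio (MMR) counts. Observed counts follow a
    Poisson likelihood whose log relative risk decomposes into an overall
    level, a spatially structured intrinsic conditional autoregressive (ICAR)
    effect, an unstructured heterogeneity effect, optional area-level covariate
    effects, a common linear time trend and area-specific trend deviations.
    Inference is by adaptive Metropolis-within-Gibbs MCMC. The package
    provides a synthetic-data generator on contiguity graphs, exceedance
    probability hot-spot classification, DIC model comparison, per-area trend
    regressions, heatmap standardization, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
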