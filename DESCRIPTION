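Package: localdiff
Title: Localized Difference Between National Air-Pollution Predictions and
    Mobile-Monitoring Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the localized difference (LD) between block-group
    level national land-use-regression (LUR) predictions of NO2 and
    ultrafine-particle (UFP) concentrations and hyperlocal mobile-monitoring
    observations aggregated to a 100 m grid, and relates LD to known local
    pollution sources and neighborhood demographics.  Provides the drive-pass
    median gridding protocol, area-weighted harmonization of block-group
    predictions and census demographics onto the monitoring grid, buffered
    source-density features, a Bayesian Additive Regression Trees (BART)
    sum-of-trees MCMC sampler with partial dependence and posterior credible
    bands, variable-inclusion proportions, population-weighted exposure
    summaries, and a synthetic-scene generator with known ground truth for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
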