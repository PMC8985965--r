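Package: injuryprofiles
Title: Latent Class Injury Profiling for Combat Casualty Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for profiling co-occurring injuries in casualty cohorts.
    Codes injury records into the extended Barell Injury Diagnosis Matrix
    (36 body regions by 13 natures of injury, with open and closed fractures
    split), computes Injury Severity Scores and severity categories, fits
    latent class models (mixtures of independent Bernoulli indicators) by
    expectation-maximization with multiple restarts, scores candidate class
    counts with BIC, sample-size-adjusted BIC, AIC, and consistent AIC plus
    relative entropy and classification diagnostics, labels classes as injury
    profiles via a conditional-probability threshold, and compares covariate
    distributions across profiles with chi-square tests and Holm-adjusted
    pairwise comparisons. A seeded synthetic-cohort generator with a
    documented latent-class structure supports end-to-end testing without
    access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
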