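Package: qcindex
Title: Quality of Care Index Construction from Epidemiologic Burden Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a 0-100 Quality of Care Index (QCI) for a disease from
    long-format epidemiologic burden panels (incidence, prevalence, deaths,
    DALY, YLL, YLD with 95% uncertainty intervals). Four secondary care-quality
    ratios (mortality-to-incidence, DALY-to-prevalence,
    prevalence-to-incidence, YLL-to-YLD) are standardized and combined through
    the first principal component of their correlation matrix, oriented so that
    higher scores mean better care, and min-max rescaled to 0-100. Includes
    gender disparity ratios, age-group and SDI-quintile disparity analytics,
    leave-one-out outlier flagging, uncertainty-interval overlap significance
    testing, direct age-standardization, a mixed-effects validation harness,
    and a seeded generator of GBD-like synthetic panels with known latent care
    quality for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    lme4,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
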