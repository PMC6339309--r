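Package: latuse
Title: Latent-Class Measurement of Latrine Use with Pseudo-Class Pooled
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures a sensitive sanitation behaviour -- consistent latrine
    use -- as a latent class from polytomous psychosocial survey indicators,
    and carries the uncertainty of latent assignment through to a pooled
    regression against household sanitation access.  Provides an EM fitter
    for mixtures of independent multinomials with full-information maximum
    likelihood under item missingness, observed-information and
    cluster-robust standard errors, relative entropy and parametric-bootstrap
    goodness-of-fit diagnostics, a confidence-interval-overlap rule for
    pruning uninformative indicators, pseudo-class multiple imputation of
    class membership, Rubin-rules pooling of household-clustered logistic
    regressions, a two-step polychoric correlation estimator, and a
    synthetic-survey generator calibrated to a published two-class model of
    latrine use in rural Ecuador.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    mvtnorm,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
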