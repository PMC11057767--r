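Package: bqridge
Title: Bootstrap-Quantile Selection of the Ridge Biasing Parameter
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ridge regression under multicollinearity with the biasing
    parameter chosen as an empirical quantile of its nonparametric pairs
    bootstrap distribution. Implements five classical ridge-parameter rules
    (Hoerl-Kennard, Hoerl-Kennard-Baldwin, Hocking-Speed-Lynn, and the
    arithmetic- and geometric-mean rules), their bootstrap-quantile
    improvements, the canonical-form mean-squared-error machinery needed to
    compare them, a Monte Carlo engine for collinear Gaussian designs with
    normal and heavy-tailed errors, and collinearity diagnostics (variance
    inflation factors, condition number) for real tabular data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
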