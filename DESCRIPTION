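Package: odcea
Title: Cost-Effectiveness Analysis of Six- Versus Four-Implant Maxillary
    Overdentures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort decision model comparing bar-retained maxillary
    overdentures supported by six versus four implants. Implements triangular
    parameter distributions, annual-cycle state transitions over the remaining
    implant count, probabilistic sensitivity analysis by Monte Carlo sampling,
    cost-effectiveness acceptability curves, and extraction of the
    willingness-to-pay threshold (in euro per year of denture satisfaction)
    above which the six-implant strategy is the preferable treatment, together
    with one-way sensitivity analyses over patient-satisfaction scenarios,
    repair-period satisfaction adjustment, and treatment-complexity cost
    factors.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
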