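Package: itsar
Title: Interrupted Time Series Analysis of Prescribing Rates with
    Autoregressive Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmented regression for interrupted time series of monthly
    prescribing rates (prescriptions per 100 000 population), with
    autoregressive error structure fitted by Yule-Walker feasible
    generalized least squares. Provides generalized Durbin-Watson
    diagnostics, backward stepwise selection of the autoregressive order,
    counterfactual extrapolation of the pre-intervention trend, bootstrap
    percentile confidence intervals on the mean percentage change in use,
    and the Altman-Bland test for interaction between subgroup effects.
    Includes a synthetic-data generator that emulates the statistical
    structure of drug-utilisation panels so the full pipeline can be
    exercised without access-restricted claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
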