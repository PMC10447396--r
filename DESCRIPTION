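Package: heatasthma
Title: Time-Stratified Case-Crossover Analysis of Summer Temperature and
    Asthma Hospitalisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying short-term effects of warm ambient
    temperature on asthma hospital admissions with a time-stratified
    case-crossover design. Includes a synthetic-data generator with known
    ground truth (gridded daily temperatures, coarse meteorological
    confounders, a patient population and Poisson admission events), an
    exclusion cascade and exposure-linkage step (lag-averaged daily mean
    temperature at the residential grid cell), construction of
    same-weekday/month/year referent strata, Bayesian conditional Poisson
    inference via a Laplace approximation (with an optional
    Metropolis-Hastings backend and a random-walk-2 smooth
    exposure-response sensitivity analysis), subgroup analyses by age,
    sex, period and region, a posterior-draw yearly-trend procedure, and
    a one-call pipeline that writes tidy result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
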