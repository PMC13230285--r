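Package: dcisnat
Title: Joint Natural-History Modelling of Ductal Carcinoma in Situ and
    Invasive Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Continuous tumour-growth modelling of the joint natural history
    of ductal carcinoma in situ (DCIS) and invasive breast cancer in a stable
    disease population.  Provides power-law DCIS and exponential invasive
    growth kinetics with a Gamma-distributed individual inverse growth rate,
    size-proportional competing hazards for symptomatic DCIS detection and
    transition to invasiveness, closed-form symptomatic-size densities,
    stationary preclinical size distributions and membership probabilities, a
    chunked microsimulator of the stable population under mammography
    screening with logistic size-dependent sensitivity, conditional
    incident-cases likelihood contributions for the four detection classes
    (screen/symptomatic x DCIS/invasive) with screening-history
    back-projection, and maximum-likelihood estimation with recovery
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
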