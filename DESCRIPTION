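Package: ohctitle
Title: Causal Effect of Honorary Titles on Physician Service Volumes in
    Online Health Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the causal effect of an honorary-title
    incentive on physicians' monthly service volumes (online consultations
    and home-page views) in an online health community.  Implements the full
    design: a seeded synthetic panel generator with selection on observables,
    maximum-likelihood logistic propensity-score estimation, greedy 1:N
    nearest-neighbour matching without replacement with absolute
    standardized-difference balance diagnostics, sharp regression
    discontinuity estimation at the award month (global polynomial and
    kernel-weighted local linear, cluster-robust standard errors), the
    differential (treated-minus-control) treatment effect, and a lag scan
    for delayed discontinuities.  A single pipeline driver orchestrates all
    stages reproducibly from one configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
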