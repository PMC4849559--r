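Package: stablecad
Title: Lifetime Decision Model for Stable Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lifetime multi-state decision model for patients with stable
    coronary artery disease (stable-CAD). Generates synthetic cohorts with
    the covariate structure of linked electronic health records, fits eleven
    parametric competing-risk survival equations (exponential, Weibull,
    lognormal and generalised gamma, selected by AIC), composes cause-specific
    hazards into cumulative incidence functions, and runs a six-state Markov
    cohort model in 90-day cycles to predict remaining lifetime costs,
    quality-adjusted life years and cardiovascular endpoint probabilities
    stratified by baseline cardiovascular risk. Includes an individual-level
    microsimulation oracle, probabilistic sensitivity analysis, and
    value-based maximum-price calculation for hypothetical risk-reducing
    treatments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
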