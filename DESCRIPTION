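Package: smokesim
Title: Discrete-Time Simulation of Daily and Nondaily Smoking Under
    Tobacco Control Policies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-time, first-order Markov cohort model of cigarette
    smoking prevalence that distinguishes daily from nondaily smokers.
    Evolves an age-by-gender population through births, deaths and
    migration, and smoking-state occupancy through initiation, cessation
    and relapse by years quit.  A policy engine converts MPOWER-style
    tobacco-control timelines (taxes via price elasticities, smoke-free
    air laws, media campaigns, marketing restrictions, health warnings,
    cessation treatment, youth access) into first-year prevalence shocks
    and ongoing initiation/cessation multipliers, with coverage and
    enforcement scaling and non-additive combination.  Includes status-quo
    versus counterfactual comparison, per-policy attribution, survey
    validation, smoking-attributable death accounting, and a calibrated
    synthetic-baseline generator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
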