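Package: meropta
Title: Meropenem In-Bottle Degradation Kinetics and Continuous-Infusion
    Target Attainment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage pharmacometric pipeline for meropenem prolonged
    infusion. Stage one estimates first-order in-bottle degradation
    kinetics of reconstituted meropenem across temperature, infusion
    concentration and product brand with linear mixed-effects models
    (maximum likelihood, likelihood-ratio model selection, parametric
    bootstrap confidence intervals, per-run conditional modes), including
    a synthetic-data generator reproducing the full factorial stability
    design. Stage two integrates the estimated degradation rate constant
    into a two-compartment population-pharmacokinetic Monte Carlo
    simulation with degradation-modified infusion input, and quantifies
    probability of target attainment (98% fT>MIC) for continuous infusion
    with bottle renewal versus extended infusion across dose, MIC,
    temperature and renal-function scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
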