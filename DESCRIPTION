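Package: patchpk
Title: Population Pharmacokinetics of a Weekly Contraceptive Transdermal Patch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-route one-compartment population pharmacokinetic models for
    ethinyl estradiol (EE) and levonorgestrel (LNG) delivered by a weekly
    transdermal delivery system. Provides closed-form and ODE solutions of the
    structural models with multi-dose superposition, population simulation of a
    12-week extended regimen with interindividual variability, noncompartmental
    analysis (linear-up/log-down AUC, Cmax, Tmax, average steady-state
    concentration, accumulation ratios) with arithmetic and geometric summaries,
    a synthetic clinical-trial generator emulating a cycle-2 rich-sampling
    design, and two-stage and Laplace nonlinear mixed-effects estimators with
    goodness-of-fit and visual-predictive-check diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
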