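Package: ctqsp
Title: Translational Modelling of Antineoplastic Drug-Induced Systolic Dysfunction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A quantitative systems pharmacology platform that translates
    hiPSC-derived cardiomyocyte (hiPSC-CM) toxicity time courses into
    predictions of drug-induced left-ventricular ejection fraction (LVEF)
    reduction in virtual patients. The package implements a mechanistic
    toxicodynamic model of cardiomyocyte injury, bioenergetics and
    chemo-mechanical energy transduction for doxorubicin and trastuzumab,
    cellular drug-exposure kinetics, a two-stage least-squares calibration
    scheme with a matching synthetic in-vitro data generator, surrogate
    physiologically based pharmacokinetic and cardiac response layers, and a
    Monte-Carlo virtual-patient trial engine with subgroup incidence,
    dose-response and local sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    parallel,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
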