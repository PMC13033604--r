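Package: abscopalQSP
Title: Whole-Body PBPK-QSP Modelling of Radiotherapy-Induced Abscopal
    Tumor Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates two immunologically coupled tumors and organ-level
    immune-cell trafficking in the mouse using a physiologically based
    pharmacokinetic (PBPK) compartment network joined to a quantitative
    systems pharmacology (QSP) core of tumor-immune interactions.
    Radiotherapy is applied as instantaneous linear-quadratic dose events
    to the local tumor and/or the lymph nodes.  The package calibrates the
    model to tumor-growth cohorts by log-space genetic-algorithm
    minimisation of a sum-of-squared-errors objective with bootstrap
    resampling, generates synthetic bilateral-flank melanoma cohorts, and
    provides one-at-a-time sensitivity analysis (time-integrated total
    variance) and bootstrap-stable Spearman correlation analysis of
    inter-group treatment differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
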