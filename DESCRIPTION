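Package: vilocea
Title: Cost-Effectiveness of Vilobelimab in Mechanically Ventilated
    COVID-19 Patients
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing
    vilobelimab plus standard of care against standard of care alone
    (both with immunomodulators) in mechanically ventilated COVID-19
    patients. A 60-day acute-care decision tree (ICU stay, renal
    replacement therapy, drug acquisition) feeds a lifetime two-state
    (alive/dead) Markov cohort model with monthly cycles, half-cycle
    correction, life-table background mortality, age-dependent
    utilities and four years of post-discharge disutility. Produces
    costs, life years, QALYs, equal-value life years and the
    incremental cost-effectiveness ratio, with one-way deterministic
    sensitivity analysis (tornado), probabilistic sensitivity analysis
    and cost-effectiveness acceptability curves. Includes synthetic
    life-table generators with closed-form life expectancies for
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
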