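Package: codingintensity
Title: Risk-Adjusted Excess Coding Intensity of Inpatient Procedures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies excess coding intensity of additional inpatient
    procedures from administrative claims. A patient-level zero-inflated
    Poisson model yields a per-visit excess coding intensity residual (ECI:
    observed minus expected additional procedure count); a facility-level
    linear adjustment yields the adjusted residual (AECI). Includes a
    synthetic claims generator emulating a hip/knee arthroplasty cohort,
    preprocessing (complete-case filtering, rare-category collapsing,
    log length-of-stay, reference-coded design matrices), a from-scratch
    zero-inflated Poisson maximum-likelihood engine with Wald IRR/OR
    inference, facility ranking, and seasonal/regional aggregation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
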