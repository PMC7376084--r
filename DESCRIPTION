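Package: fraxpath
Title: FRAX-Based Case Finding with Age-Dependent Intervention Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probability-based osteoporosis case finding in the
    style of the National Osteoporosis Guideline Group (NOGG) pathway. A
    transparent competing-risk engine computes 10-year probabilities of hip
    and major osteoporotic fracture from clinical risk factors, body mass
    index and (optionally) femoral-neck bone density, as an explicit,
    configurable surrogate for closed FRAX calculators. On top of the engine
    the package derives age-dependent intervention and assessment thresholds
    with ethnic population weighting, stochastically imputes missing risk
    factors by regression on a fully observed reference cohort, triages a
    cohort through the bone-density referral algorithm, audits dispositions,
    and checks calibration of expected versus observed hip fractures.
    Includes seeded synthetic-cohort generators for end-to-end exercises.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
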