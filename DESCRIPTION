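Package: mirdose
Title: Preclinical Radioimmunoconjugate Dosimetry and Dose Planning
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for preclinical internal dosimetry of radiolabeled
    antibodies: conversion of raw gamma-counter and conjugate-view planar
    gamma-camera counts into percent-injected-dose time-activity curves,
    noncompartmental pharmacokinetic analysis, humanization of fractional
    injected activity from nonhuman primates to a reference adult, blood-based
    red-marrow and remainder-of-body time-integrated activity coefficients, a
    simplified pure-beta MIRD absorbed-dose engine, identification of the
    dose-limiting organ and maximum administrable activity under organ dose
    limits, interspecies body-surface-area dose conversion, saturation-binding
    Kd estimation, and a synthetic-data generator with known ground truth for
    validating every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
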