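Package: aspektr
Title: Quantitative Videofluoroscopic Swallowing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative analysis of videofluoroscopic swallowing
    studies in the ASPEKT tradition: derivation of timing, hyoid-kinematic and
    anatomically scaled pixel-based parameters from per-bolus annotations,
    dual-rater agreement statistics (percent absolute agreement, mean absolute
    difference, two-way random absolute-agreement intraclass correlation) with
    threshold-based discrepancy flagging and consensus merging, hierarchical
    age/sex/sip-volume regression with Bonferroni-corrected outcome families,
    and a calibrated synthetic cohort generator so the whole pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
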