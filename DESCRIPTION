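Package: jurisdea
Title: Technical-Efficiency Analysis of Health-Jurisdiction Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Output-oriented BCC (variable-returns-to-scale) data
    envelopment analysis of jurisdiction-year panels, solved per calendar
    year by explicit envelopment linear programs, with Simar-Wilson
    smoothed homogeneous bootstrap bias correction and confidence
    intervals. Bias-corrected efficiency is then explained from contextual
    covariates by a cross-validated random-forest determinants analysis
    with perturbation variable importance and partial dependence, overall
    and within socioeconomic regions, and summarized into yearly and
    regional tables (growth rates, trend tests, between-region tests). A
    seeded synthetic panel generator with a known Cobb-Douglas frontier
    and context-driven inefficiency provides ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
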