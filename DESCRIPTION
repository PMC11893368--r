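Package: celiacdq
Title: HLA-DQ Genotype Interpretation and Decision Support for Inconclusive Pediatric Celiac Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting HLA-DQA1/DQB1 typings as celiac-disease
    risk categories (DQ2.5 in cis or trans, DQ2.2, DQ8, DQ7.5), banding
    anti-transglutaminase-2 IgA serology against the assay's upper limit of
    normal, and executing the rule-based diagnostic flowcharts used for
    four groups of pediatric patients whose serology, histology and biopsy
    availability leave the conventional celiac work-up inconclusive.
    Includes a deterministic 80-patient fixture cohort reconstructed from
    published group-level counts, a stochastic cohort simulator, and
    cohort-level analytics: contribution rates, allele-distribution tables,
    exact binomial sign tests and Pearson chi-square tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
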