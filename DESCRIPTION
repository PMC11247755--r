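Package: pathresp
Title: Pathological Response Grading and Outcome Analysis for Neoadjuvant
    Chemotherapy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating pathological response to neoadjuvant
    chemotherapy in locally advanced cervical cancer from resection and
    biopsy data. Implements tumor-bed composition handling (slide averaging,
    increment rounding), the four-tier pathological response grading
    (cPR/mPR/pPR/nPR) with good/poor binarization, post-treatment stromal
    typing (inflammatory/fibrotic/necrotic/intermediate), pre-treatment
    biomarker scoring (stromal TILs grade, TILV, IHC densities and ratios,
    PD-L1 CPS/TPS/IPS), RECIST-style radiological categorization, the
    cross-sectional association battery (Fisher/chi-square selection,
    Spearman, Kruskal-Wallis, logistic regression with odds ratios),
    Kaplan-Meier/log-rank/Cox survival analysis, and a synthetic cohort
    generator that reproduces the statistical structure the analysis
    assumes so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
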