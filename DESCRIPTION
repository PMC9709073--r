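Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance workflow for quarterly FAERS
    (FDA Adverse Event Reporting System) ASCII extracts: parsing and
    case-version deduplication, primary-suspect cohort construction for a
    target drug, report-level 2x2 contingency tables at the MedDRA preferred
    term and system organ class levels, four disproportionality estimators
    (reporting odds ratio, proportional reporting ratio with chi-squared,
    Bayesian confidence propagation information component, and gamma-Poisson
    shrinkage EBGM), signal classification against configurable thresholds
    and a product-label term list, time-to-onset summaries, a consumer-report
    sensitivity variant, a synthetic report generator with known ground
    truth, and a contingency-reconstruction oracle that back-solves
    comparator cells from published (count, cohort size, ROR, CI) values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
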