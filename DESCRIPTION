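Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pharmacovigilance toolkit for FAERS-style spontaneous
    adverse-event report databases: parsing of quarterly multi-table ASCII
    extracts, case deduplication by CASEID/FDA_DT/PRIMARYID, drug- and
    indication-restricted cohort extraction, 2x2 contingency tables at the
    MedDRA preferred-term and system-organ-class levels, and the three
    classical disproportionality estimators (reporting odds ratio,
    proportional reporting ratio with 1-df chi-square, and the Bayesian
    confidence propagation information component with its lower credibility
    bound). Includes multi-method signal classification with
    Benjamini-Hochberg false-discovery-rate control, stratified subgroup
    analysis with Cochran-Mantel-Haenszel common odds ratios and
    Breslow-Day-Tarone homogeneity tests, time-to-onset binning, descriptive
    cohort summaries, and a seeded synthetic report generator with injectable
    true reporting odds ratios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
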