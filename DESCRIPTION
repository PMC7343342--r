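Package: vocclaims
Title: Vaso-Occlusive Crisis Episode and Cost Analytics for Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective administrative-claims analysis of
    vaso-occlusive crisis (VOC) burden in adult sickle cell disease (SCD):
    cohort construction with index-date and continuous-enrollment logic,
    gap-based merging of discrete VOC claims into episodes of care with
    hierarchical place-of-service classification, Charlson Comorbidity
    Index scoring and baseline clinical characterization, CPI-adjusted
    all-cause and SCD-related utilization and cost summaries stratified by
    episode frequency, and per-episode costs by care setting. Includes a
    seedable synthetic Medicaid-style claims generator with recoverable
    ground truth so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
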