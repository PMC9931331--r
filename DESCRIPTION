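Package: dsaudit
Title: Provenance Audit of Hospital Discharge Summaries
Version: 0.1.0
Authors@R:
    person("dsaudit", "maintainers", email = "dsaudit@example.org", role = c("aut", "cre"))
Description: Tools to audit whether the information in hospital discharge
    summaries can be reconstructed from the inpatient (progress-note) records
    of the same admission. Documents are split into sentences and fine-grained
    clinical segments; each summary segment is scored by word bi-gram coverage
    against the patient's inpatient records and classified as sourced or
    unsourced; a multitask classifier assigns subjectivity, clinical-role and
    probable labels with a weighted-sum cross-entropy loss; and stratified
    reports break the unsourced rate down by label, section, hospital and
    external source document. A seeded synthetic-corpus generator plants
    recoverable ground truth so that every pipeline stage is testable without
    access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
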