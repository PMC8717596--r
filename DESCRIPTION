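Package: hacbench
Title: Benchmarking Hospital Patient Safety from Hospital-Acquired
    Complications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking the patient-safety performance of
    hospitals from linked administrative admission data. Flags
    hospital-acquired complications (HACs) from ICD-10 diagnosis codes and
    condition-onset flags, computes Charlson comorbidity and admission
    complexity indices, benchmarks hospitals with output-oriented data
    envelopment analysis under regional (group) and state (meta) frontiers,
    derives peers, targets and peer networks, and fits logistic and
    log-link generalised linear models for the effects of complications on
    mortality, readmission, cost and length of stay. Includes a synthetic
    admissions-cohort generator with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    digest
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
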