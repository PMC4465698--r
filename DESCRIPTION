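Package: poagphen
Title: Rule-Based Phenotyping of Primary Open-Angle Glaucoma from
    Electronic Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies primary open-angle glaucoma (POAG) cases and
    controls in longitudinal electronic medical records using a
    rule-based decision tree over ICD-9 diagnosis codes, CPT procedure
    codes, medication mentions, and free clinical text.  Includes
    definite/potential case adjudication against chart-review style
    criteria, extraction of cup-to-disc ratio measurements with
    laterality from clinic notes, index-date and windowed covariate
    derivation, chart-review performance metrics (PPV, NPV, sensitivity,
    specificity, accuracy), and a seeded generator of labeled synthetic
    EMR cohorts that exercises every branch of the algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
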