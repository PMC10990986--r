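Package: aiscore
Title: Automated Scoring of Autobiographical Interview Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores Autobiographical Interview narratives automatically by
    classifying each sentence into one of four internal-content proportion
    classes (0, 50, 75 or 100 percent internal), converting class predictions
    into internal and external word counts, and aggregating them per
    narrative. Includes training-data preparation (sentence splitting,
    long-sentence filtering, class balancing by upsampling), a pluggable
    sentence-classifier backend, four-quadrant correlation validation
    against manual detail counts, leave-one-dataset-out cross-validation,
    and a synthetic annotated-corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    Matrix,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
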