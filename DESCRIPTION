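Package: rwdminer
Title: Mining Structured and Free-Text Electronic Health Records for
    Drug-Safety Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for comparing the clinical
    information retrievable from structured hospital tables (diagnosis
    records carrying ICD-10 codes and medication orders) against free-text
    discharge summaries. Provides a deterministic dictionary-based entity
    tagger with rule-based negation filtering, fuzzy normalization of
    mention surfaces and medication product names to medical concepts via
    the normalized Levenshtein score with a cutoff of 70, per-source entity
    and concept frequency reports, three-source patient cohort
    identification with Venn region counts, and drug-pair by symptom
    co-frequency ratio matrices for adverse-drug-effect signal screening.
    Ships a synthetic electronic-health-record generator with exact ground
    truth so the full pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
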