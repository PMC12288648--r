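Package: resppheno
Title: Computational Phenotyping of ICU Respiratory Support Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end computational-phenotyping pipeline for acute
    respiratory failure (ARF) respiratory-support therapies in ICU
    encounters. Builds templated "constructed concepts" from nine
    eICU-style EHR tables, classifies encounters into eight
    therapy-sequence phenotypes (invasive mechanical ventilation,
    noninvasive positive pressure ventilation, high-flow nasal
    insufflation, their failure/transition sequences, or none) with a
    deterministic rule-based reference algorithm, and exposes a
    pluggable classification-backend contract (chain-of-thought prompt
    assembly, answer parsing, oracle and noisy test doubles, and a
    local language-model client) for concept selection and
    description-based phenotyping. Includes a synthetic EHR generator
    with planted ground-truth phenotypes and a one-vs-rest
    AUROC/sensitivity/specificity evaluation harness, so the whole
    pipeline is testable offline.
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
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    curl,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
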