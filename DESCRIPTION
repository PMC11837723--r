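Package: sfratio
Title: Evaluating the SpO2/FiO2 Ratio as a Surrogate for the PaO2/FiO2
    Ratio in ARDS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the pulse-oximetric SpO2/FiO2 (SF) ratio as a
    surrogate for the arterial PaO2/FiO2 (PF) ratio in severity
    classification and monitoring of the acute respiratory distress
    syndrome (ARDS). Implements the oxygenation physiology (Severinghaus
    oxyhemoglobin dissociation curve, alveolar gas equation, Respiratory
    Index), time-matching of intermittent arterial blood-gas events with
    continuous SpO2/FiO2 signals, ordinal severity classification under
    the 2024 global-definition thresholds, datapoint- and admission-level
    agreement analysis, trending analysis under a Respiratory-Index
    stability gate, SF-to-PF conversion equations, and a physiology-based
    synthetic ICU cohort generator that emulates clinician FiO2 titration
    and heteroscedastic oximeter error so the full pipeline is testable
    without access-restricted ICU databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
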