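Package: trialgender
Title: Extraction and Summarization of Gender Requirements from Clinical Trial Text
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting, verifying and summarizing gender eligibility
    requirements -- in particular transgender recruitment requirements -- from
    unstructured clinical trial registry text. Implements a 13-type virtual
    gender model extending the conventional Male/Female/All registration
    options, lexicon- and rule-based gender mention detection with partner and
    negation context verification, automatically learned windowed transgender
    matching patterns filtered by support and confidence, frequency-based
    majority-rule summarization of mentions into a single gender requirement
    per trial, and a macro-averaged multi-class evaluation harness with
    stratified k-fold cross-validation and threshold tuning. Includes a
    synthetic fixture generator emulating registry-style trial records so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
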