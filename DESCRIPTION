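Package: medspell
Title: Context-Aware Typographical Error Correction for Medical Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dictionary-based correction of typographical errors in
    unstructured medical text, combining a SymSpell-style delete-neighborhood
    candidate index with restricted Damerau-Levenshtein verification and a
    masked-context candidate score blended with a frequency score. Includes a
    reproducible typo-injection model (insert, delete, replace, transpose with
    balanced type counts), BIO/CoNLL named-entity utilities with a trainable
    baseline sequence tagger, tumor-size post-processing for surgical
    pathology records, evaluation harnesses quantifying how typo rate degrades
    entity extraction and how correction recovers it, and deterministic
    synthetic corpus generators for offline experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
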