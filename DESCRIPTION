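Package: tnmkb
Title: TNM Staging Knowledge Base and Cancer-Registry Record Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An executable knowledge base and saturation-based inference
    engine for TNM staging of summary cancer-registry records. Rule modules
    written in a small declarative text format encode ICD-O-3 topography and
    morphology hierarchies, morphology categories, TNM sites, per-site and
    per-edition T/N/M code spaces, and stage-group rules as general concept
    inclusions. The engine classifies case records to TNM sites and stage
    groups by forward-chaining to a least fixpoint, validates declared stage
    and T/N/M codes against the edition-specific rules, proposes corrections
    for records with recognised stage groups, generates labelled synthetic
    record batches for testing, and exports the compiled rule set in OWL 2
    functional syntax.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
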