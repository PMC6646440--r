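Package: radfacts
Title: Complete Fact-Level Information Extraction from Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting complete, contextualized clinical facts
    from free-text radiology reports. A fact is a clinical assertion (a
    finding was observed, a follow-up was recommended, a diagnosis is
    carried) represented as a contiguous token span containing one anchor
    entity span and zero or more modifier spans (negation, uncertainty,
    location, size, change over time, ...). The package provides an
    extensible fact schema, a token-level standoff annotation format, a
    synthetic gold-annotated report generator, subword (character n-gram)
    skip-gram embeddings robust to typos and out-of-vocabulary terms, a
    two-stage recurrent neural extractor (document-level fact/anchor
    tagging followed by per-fact-type span refinement and modifier slot
    filling), training with early stopping, and token-level micro-averaged
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
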