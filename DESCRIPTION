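Package: fcatopics
Title: Multi-Topic Assignment and Conjunctive Navigation for Consumer
    Health Questions with Formal Concept Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns multiple health topics to consumer health questions by
    combining semantic concept (CUI) annotation, TF-IDF and term-strength
    concept filtering, and Formal Concept Analysis (FCA). Provides formal
    contexts with Galois derivation operators and full concept-lattice
    enumeration (NextClosure), a dictionary concept annotator with
    semantic-type exclusion, a concept-extent voting scheme for topic
    assignment, example-based multi-label evaluation metrics, a conjunctive
    (chained-context) navigation engine, and a synthetic corpus generator
    with known multi-topic ground truth.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
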