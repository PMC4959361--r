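Package: conceptrf
Title: Concept-Based Relevance-Feedback Retrieval for Biomedical Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks concept-annotated documents against complex topic queries
    and refines the ranking from explicit user feedback. Documents are bags of
    sentences whose tokens are standardised biomedical concept identifiers
    (UMLS CUIs or any opaque tokens); the initial ranking uses accumulative
    TF-IDF over the query concepts, user-selected documents are mined with a
    weighted-interest association measure into top-k concept profiles, and all
    documents are re-ranked by truncated rank-biased overlap against the
    feedback profile while user selections are retained in the top list across
    rounds. Includes a parser for MetaMap-style concept-mapping output, a
    TREC-qrels reader, a mean-average-precision evaluation harness with a
    simulated user, and a synthetic corpus generator with planted relevant
    documents for offline testing.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
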