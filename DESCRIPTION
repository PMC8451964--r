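Package: multiret
Title: Multistage Retrieval for Biomedical Literature Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multistage information-retrieval toolkit for biomedical
    literature collections in the style of the TREC-COVID challenge.
    Implements first-stage probabilistic ranking over a field-aware
    inverted index (Okapi BM25, divergence-from-randomness with a
    geometric randomness model, and Dirichlet-smoothed query-likelihood
    language models), a combinatorial topic-field querying strategy with
    synonym expansion and publication-date filtering, reciprocal rank
    fusion of ranked lists, a pluggable second-stage reranker contract
    with feature-level logistic score fusion, graded-relevance evaluation
    (P@K, NDCG@K, MAP, Bpref), and a deterministic synthetic
    corpus/topic/qrels generator so the whole pipeline is testable
    without any external collection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
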