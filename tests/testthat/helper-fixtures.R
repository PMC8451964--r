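# Small programmatic fixtures shared across test files.

tiny_corpus <- function() {
  tibble::tibble(
    doc_id = c("a", "b", "c"),
    title = c("covid test", "covid", "influenza vaccine"),
    abstract = c("a covid study of testing", "another covid abstract",
                 "seasonal influenza"),
    full_text = c(NA, "full body text about covid transmission", NA),
    publish_date = as.Date(c("2020-01-15", "2019-11-30", "2020-03-01")),
    source = c("medline", "pmc", "who")
  )
}

tiny_topics <- function() {
  tibble::tibble(
    number = 1L,
    query = "covid testing",
    question = "what is known about covid testing?",
    narrative = "studies reporting covid test results"
  )
}

# random word-like vocabulary; digits keep the stemmer out of the way
rand_vocab <- function(n) paste0(sample(letters, n, replace = TRUE),
                                 sample(letters, n, replace = TRUE),
                                 seq_len(n))

rand_corpus <- function(n_docs, vocab, date_frac_na = 0.1) {
  mk <- function(len) {
    vapply(seq_len(n_docs), function(i) {
      paste(sample(vocab, len, replace = TRUE), collapse = " ")
    }, character(1))
  }
  dates <- as.Date("2020-01-01") + sample(0:180, n_docs, replace = TRUE)
  dates[runif(n_docs) < date_frac_na] <- NA
  tibble::tibble(
    doc_id = sprintf("r%03d", seq_len(n_docs)),
    title = mk(4),
    abstract = mk(15),
    full_text = ifelse(runif(n_docs) < 0.5, mk(40), NA_character_),
    publish_date = dates,
    source = "synthetic"
  )
}

rand_topic <- function(vocab, number = 1L) {
  tibble::tibble(
    number = number,
    query = paste(sample(vocab, 2), collapse = " "),
    question = paste(sample(vocab, 4), collapse = " "),
    narrative = paste(sample(vocab, 6), collapse = " ")
  )
}

# a random ranked list + graded judgments for metric conformance tests
rand_run_and_qrels <- function(tn = 1L, n_pool = 40L, n_ranked = 25L,
                               n_judged = 20L) {
  n_ranked <- min(n_ranked, n_pool)
  n_judged <- min(n_judged, n_pool)
  pool <- sprintf("p%03d", seq_len(n_pool))
  ranked <- sample(pool, n_ranked)
  run <- tibble::tibble(topic = tn, doc_id = ranked,
                        rank = seq_len(n_ranked),
                        score = rev(sort(runif(n_ranked))), tag = "rand")
  judged <- sample(pool, n_judged)
  qrels <- tibble::tibble(topic = tn, doc_id = judged,
                          grade = sample(0:2, n_judged, replace = TRUE,
                                         prob = c(0.5, 0.3, 0.2)))
  list(run = run, qrels = qrels)
}

small_spec <- function(seed = 7L) {
  synthetic_spec(seed = seed, vocab_size = 200L, n_themes = 5L,
                 docs_per_theme = 12L, judged_nonrel_per_topic = 5L)
}
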