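test_that("index statistics match hand counts after normalization", {
  corpus <- tibble::tibble(
    doc_id = c("d1", "d2"),
    title = c("covid test", "covid"),
    abstract = c("", ""), full_text = NA_character_,
    publish_date = as.Date(NA), source = ""
  )
  idx <- build_index(corpus, "metadata")
  title <- idx$fields$title
  expect_equal(title$df[["covid"]], 2L)
  expect_equal(title$cf[["covid"]], 2)
  expect_equal(title$avg_len, 1.5)
  expect_equal(title$postings[["covid"]]$doc, c(1L, 2L))
  # absent term: no posting list
  expect_null(title$postings[["influenza"]])
  # single-doc corpus: avg_len is that document's length
  idx1 <- build_index(corpus[1, ], "metadata")
  expect_equal(idx1$fields$title$avg_len, 2)
})

test_that("index invariants hold on random corpora", {
  set.seed(21)
  corpus <- rand_corpus(30, rand_vocab(60))
  for (kind in c("metadata", "fulltext")) {
    idx <- build_index(corpus, kind)
    for (f in idx$fields) {
      expect_equal(f$avg_len, mean(f$doc_len))
      expect_equal(f$total_terms, sum(f$doc_len))
      for (term in names(f$postings)) {
        p <- f$postings[[term]]
        expect_equal(sum(p$tf), unname(f$cf[term]))
        expect_equal(length(p$doc), unname(f$df[term]))
        expect_lte(f$df[[term]], f$n_docs)
      }
      # collection frequency over postings equals total length
      expect_equal(sum(f$cf), f$total_terms)
    }
  }
  expect_error(build_index(corpus[0, ], "metadata"), class = "mr_config_error")
})

test_that("full-text index folds the body into the abstract section", {
  corpus <- tiny_corpus()
  meta <- build_index(corpus, "metadata")
  full <- build_index(corpus, "fulltext")
  expect_false("transmiss" %in% names(meta$fields$abstract$postings))
  expect_true("transmiss" %in% names(full$fields$abstract$postings))
  expect_true("transmiss" %in% names(full$fields$whole$postings))
})

test_that("index persists to its versioned on-disk layout", {
  idx <- build_index(tiny_corpus(), "fulltext")
  path <- withr::local_tempfile(fileext = ".json")
  save_index(idx, path)
  back <- load_index(path)
  expect_equal(back$doc_ids, idx$doc_ids)
  expect_equal(back$dates, idx$dates)
  for (f in names(idx$fields)) {
    expect_equal(back$fields[[f]]$doc_len, idx$fields[[f]]$doc_len)
    expect_equal(back$fields[[f]]$cf, idx$fields[[f]]$cf)
    expect_equal(names(back$fields[[f]]$postings), names(idx$fields[[f]]$postings))
  }
  # scores from a reloaded index are identical
  topic <- tiny_topics()
  r1 <- search_index(idx, topic, weighting_model("bm25"))
  r2 <- search_index(back, topic, weighting_model("bm25"))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  # version guard
  bad <- withr::local_tempfile(lines = '{"format":"other","version":9}')
  expect_error(load_index(bad), class = "mr_format_error")
})

test_that("query plan is the 7-way field/section combinatorial design", {
  plan <- make_query_plan(tiny_topics(), "metadata")
  expect_length(plan, 7L)
  expect_equal(
    vapply(plan, function(s) paste(s$source, s$target, sep = ">"), character(1)),
    c("query>title", "query>abstract", "question>title", "question>abstract",
      "narrative>title", "narrative>abstract", "all>whole")
  )
  # concatenated spec is the concatenation of the three field term sequences
  topic <- tiny_topics()
  expect_equal(plan[[7]]$terms,
               c(normalize_terms(topic$query), normalize_terms(topic$question),
                 normalize_terms(topic$narrative)))
  # empty narrative still yields 7 specs, with empty term sequences
  t2 <- tiny_topics()
  t2$narrative <- ""
  plan2 <- make_query_plan(t2, "fulltext")
  expect_length(plan2, 7L)
  expect_equal(plan2[[5]]$terms, character())
  expect_equal(plan2[[6]]$terms, character())
})

test_that("query plan applies synonym expansion to queries", {
  tab <- synonym_table(list(c("covid", "sars-cov-2")))
  plan <- make_query_plan(tiny_topics(), "metadata", synonyms = tab)
  expect_true("sars-cov-2" %in% plan[[1]]$terms)
})

test_that("single matching document ranks first; score ties break by doc_id", {
  corpus <- tiny_corpus()
  idx <- build_index(corpus, "metadata")
  r <- search_index(idx, tibble::tibble(number = 1L, query = "influenza",
                                        question = "", narrative = ""),
                    weighting_model("bm25"))
  expect_equal(r$doc_id[1], "c")
  # two identical documents tie and order by doc_id
  twin <- tibble::tibble(doc_id = c("zz", "aa"), title = c("covid", "covid"),
                         abstract = "", full_text = NA_character_,
                         publish_date = as.Date(NA), source = "")
  rt <- search_index(build_index(twin, "metadata"),
                     tibble::tibble(number = 1L, query = "covid",
                                    question = "", narrative = ""),
                     weighting_model("bm25"))
  expect_equal(rt$doc_id, c("aa", "zz"))
  expect_equal(rt$score[1], rt$score[2])
})

test_that("date cutoff is half-open at 2019-12-01 and never adds documents", {
  corpus <- tibble::tibble(
    doc_id = c("early", "boundary", "late", "undated"),
    title = "covid", abstract = "", full_text = NA_character_,
    publish_date = as.Date(c("2019-11-30", "2019-12-01", "2020-02-01", NA)),
    source = ""
  )
  idx <- build_index(corpus, "metadata")
  topic <- tibble::tibble(number = 1L, query = "covid", question = "", narrative = "")
  model <- weighting_model("bm25")
  no_cut <- search_index(idx, topic, model)
  cut <- search_index(idx, topic, model, cutoff = as.Date("2019-12-01"))
  expect_setequal(no_cut$doc_id, c("early", "boundary", "late", "undated"))
  expect_setequal(cut$doc_id, c("boundary", "late", "undated"))
  strict <- search_index(idx, topic, model, cutoff = as.Date("2019-12-01"),
                         keep_undated = FALSE)
  expect_setequal(strict$doc_id, c("boundary", "late"))
  expect_lte(nrow(cut), nrow(no_cut))
  expect_lte(nrow(strict), nrow(cut))
})

test_that("search equals the formula-application oracle and ignores corpus order", {
  set.seed(99)
  vocab <- rand_vocab(40)
  corpus <- rand_corpus(25, vocab)
  topic <- rand_topic(vocab)
  for (model_name in c("bm25", "dfr", "lmd")) {
    model <- weighting_model(model_name)
    for (kind in c("metadata", "fulltext")) {
      idx <- build_index(corpus, kind)
      run <- search_index(idx, topic, model, top_k = nrow(corpus))
      expected <- oracle_search_scores(corpus, topic, model_name, model$params, kind)
      expect_equal(run$score, unname(expected[run$doc_id]), tolerance = 1e-12)
      # every document with a nonzero oracle score is returned
      expect_setequal(run$doc_id, names(expected)[expected != 0])
      # permutation invariance of corpus input order
      perm <- corpus[sample(nrow(corpus)), ]
      run_perm <- search_index(build_index(perm, kind), topic, model,
                               top_k = nrow(corpus))
      expect_equal(as.data.frame(run_perm), as.data.frame(run))
    }
  }
})

test_that("cross-validated tuning recovers length normalization", {
  # long documents stuff extra copies of each topic term, so with b = 0
  # they outrank the short truly relevant documents; b close to 1
  # penalizes the padding and restores the short documents
  n_topics <- 5L
  docs <- list()
  qrels <- list()
  for (tn in seq_len(n_topics)) {
    term <- sprintf("term%d", tn)
    short_ids <- sprintf("t%d-short%d", tn, 1:3)
    long_ids <- sprintf("t%d-long%d", tn, 1:3)
    docs[[tn]] <- tibble::tibble(
      doc_id = c(short_ids, long_ids),
      title = c(rep(term, 3),
                rep(paste(c(rep(term, 4), rep("pad1 pad2 pad3 pad4", 12)),
                          collapse = " "), 3)),
      abstract = "", full_text = NA_character_,
      publish_date = as.Date("2020-01-01"), source = ""
    )
    qrels[[tn]] <- tibble::tibble(topic = tn,
                                  doc_id = c(short_ids, long_ids),
                                  grade = c(2L, 2L, 2L, 0L, 0L, 0L))
  }
  corpus <- dplyr::bind_rows(docs)
  qrels <- dplyr::bind_rows(qrels)
  topics <- tibble::tibble(number = seq_len(n_topics),
                           query = sprintf("term%d", seq_len(n_topics)),
                           question = "", narrative = "")
  idx <- build_index(corpus, "metadata")
  grid <- data.frame(k1 = 1.2, b = c(0, 0.9))
  fit <- fit_params(idx, topics, qrels, "bm25", grid, folds = 5L, k_eval = 3L)
  expect_gt(fit$best$b, 0)
  expect_equal(nrow(fit$scores), 2L)
  expect_gt(fit$scores$mean_p10[2], fit$scores$mean_p10[1])
})

test_that("parameter tuning validates its inputs", {
  coll <- generate_collection(small_spec())
  idx <- build_index(coll$corpus, "metadata")
  expect_error(fit_params(idx, coll$topics, coll$qrels, "bm25",
                          data.frame()[0, ], folds = 2L),
               class = "mr_config_error")
  expect_error(fit_params(idx, coll$topics, coll$qrels, "bm25",
                          data.frame(b = 0.5), folds = 50L),
               class = "mr_config_error")
  # a one-point grid returns that point
  one <- fit_params(idx, coll$topics[1:4, ], coll$qrels, "bm25",
                    data.frame(b = 0.4), folds = 2L)
  expect_equal(one$best$b, 0.4)
})
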