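mk_topic_run <- function(docs, tn = 1L) {
  tibble::tibble(topic = tn, doc_id = docs, rank = seq_along(docs),
                 score = rev(seq_along(docs)), tag = "eval")
}

test_that("precision at K counts judged-relevant documents in the top K", {
  qrels <- tibble::tibble(topic = 1L,
                          doc_id = c("r1", "r2", "n1", "n2"),
                          grade = c(2L, 1L, 0L, 0L))
  run <- mk_topic_run(c("r1", "n1", "r2", "n2"))
  expect_equal(precision_at_k(run, qrels, 4L), 0.5)
  expect_equal(precision_at_k(mk_topic_run(c("r1", "r2")), qrels, 2L), 1)
  # short lists pad as nonrelevant; empty lists score zero
  expect_equal(precision_at_k(mk_topic_run("r1"), qrels, 10L), 0.1)
  expect_equal(precision_at_k(mk_topic_run(character()), qrels, 5L), 0)
  # unjudged documents count as nonrelevant
  expect_equal(precision_at_k(mk_topic_run(c("r1", "unjudged")), qrels, 2L), 0.5)
})

test_that("NDCG matches the hand-worked graded example", {
  # ranking grades [2, 0, 1] against a judged pool {2, 1, 1}
  qrels <- tibble::tibble(topic = 1L,
                          doc_id = c("a", "b", "c", "d"),
                          grade = c(2L, 1L, 1L, 0L))
  run <- mk_topic_run(c("a", "d", "b"))
  dcg <- 2 + 0 + 1 / 2
  idcg <- 2 + 1 / log2(3) + 0.5
  expect_equal(ndcg_at_k(run, qrels, 3L), dcg / idcg, tolerance = 1e-9)
  # perfect ordering of all judged docs scores 1
  expect_equal(ndcg_at_k(mk_topic_run(c("a", "b", "c", "d")), qrels, 4L), 1)
  # no judged relevant documents -> 0
  none <- tibble::tibble(topic = 1L, doc_id = "a", grade = 0L)
  expect_equal(ndcg_at_k(run, none, 3L), 0)
})

test_that("average precision and Bpref match hand evaluation", {
  qrels <- tibble::tibble(topic = 1L, doc_id = c("r1", "r2", "n1"),
                          grade = c(1L, 2L, 0L))
  # relevant at ranks 1 and 3, R = 2
  expect_equal(average_precision(mk_topic_run(c("r1", "x", "r2")), qrels),
               (1 + 2 / 3) / 2, tolerance = 1e-12)
  # ranking (rel, judged-nonrel, rel): Bpref = 1/2 * [(1 - 0/1) + (1 - 1/1)]
  expect_equal(bpref(mk_topic_run(c("r1", "n1", "r2")), qrels), 0.5)
  # all relevant above all nonrelevant
  expect_equal(bpref(mk_topic_run(c("r1", "r2", "n1")), qrels), 1)
  # unjudged documents are ignored in the ranked-above count
  expect_equal(bpref(mk_topic_run(c("r1", "u1", "u2", "n1", "r2")), qrels), 0.5)
  # no judged relevant: 0 with a warning
  none <- tibble::tibble(topic = 1L, doc_id = "n1", grade = 0L)
  expect_warning(ap0 <- average_precision(mk_topic_run("n1"), none))
  expect_equal(ap0, 0)
})

test_that("all four metrics agree with the loop oracle on randomized instances", {
  set.seed(31)
  for (i in 1:120) {
    inst <- rand_run_and_qrels()
    grades <- oracle_grades(inst$qrels, 1L)
    docs <- inst$run$doc_id
    k <- sample(c(3L, 5L, 10L, 20L), 1)
    expect_equal(precision_at_k(inst$run, inst$qrels, k),
                 oracle_p_at_k(docs, grades, k), tolerance = 1e-6)
    expect_equal(ndcg_at_k(inst$run, inst$qrels, k),
                 oracle_ndcg_at_k(docs, grades, k), tolerance = 1e-6)
    expect_equal(suppressWarnings(average_precision(inst$run, inst$qrels)),
                 oracle_ap(docs, grades), tolerance = 1e-6)
    expect_equal(suppressWarnings(bpref(inst$run, inst$qrels)),
                 oracle_bpref(docs, grades), tolerance = 1e-6)
  }
})

test_that("moving a relevant document above a nonrelevant one never hurts", {
  set.seed(37)
  for (i in 1:30) {
    inst <- rand_run_and_qrels()
    grades <- oracle_grades(inst$qrels, 1L)
    docs <- inst$run$doc_id
    g <- vapply(docs, function(d) {
      if (is.null(grades[[d]])) NA_integer_ else grades[[d]]
    }, integer(1))
    swaps <- which(!is.na(g[-1]) & !is.na(g[-length(g)]) &
                     g[-1] >= 1 & g[-length(g)] == 0)
    if (length(swaps) == 0) next
    j <- swaps[1]  # nonrel at j, rel at j+1: swap them upward
    improved <- inst$run
    improved$doc_id[c(j, j + 1)] <- improved$doc_id[c(j + 1, j)]
    for (k in c(5L, 10L)) {
      expect_gte(precision_at_k(improved, inst$qrels, k),
                 precision_at_k(inst$run, inst$qrels, k))
      expect_gte(ndcg_at_k(improved, inst$qrels, k),
                 ndcg_at_k(inst$run, inst$qrels, k))
    }
    expect_gte(suppressWarnings(average_precision(improved, inst$qrels)),
               suppressWarnings(average_precision(inst$run, inst$qrels)))
    expect_gte(suppressWarnings(bpref(improved, inst$qrels)),
               suppressWarnings(bpref(inst$run, inst$qrels)))
  }
})

test_that("run-level report macro-averages over judged topics", {
  qrels <- tibble::tibble(topic = c(1L, 1L, 2L, 2L),
                          doc_id = c("a", "b", "a", "c"),
                          grade = c(2L, 0L, 1L, 0L))
  run <- dplyr::bind_rows(mk_topic_run(c("a", "b"), tn = 1L),
                          mk_topic_run(c("c", "a"), tn = 2L),
                          mk_topic_run("zz", tn = 3L))  # no judgments: skipped
  report <- evaluate_run(run, qrels, ks = c(1L, 2L))
  expect_equal(nrow(report$per_topic), 2L)
  # single-topic macro average equals the topic's own value
  solo <- evaluate_run(run[run$topic == 1L, ], qrels, ks = c(1L, 2L))
  expect_equal(solo$summary[["p_at_1"]], solo$per_topic$p_at_1[1])
  expect_equal(report$summary[["p_at_1"]],
               mean(report$per_topic$p_at_1))
  expect_equal(report$summary[["map"]], mean(report$per_topic$ap))
  expect_true(all(report$per_topic$num_rel_ret <= report$per_topic$num_rel))
  # disjoint topics are an integrity error
  expect_error(evaluate_run(mk_topic_run("zz", tn = 9L), qrels),
               class = "mr_integrity_error")
})

test_that("metrics depend only on the ordering, not the score scale", {
  qrels <- tibble::tibble(topic = 1L, doc_id = c("a", "b"), grade = c(2L, 0L))
  run1 <- mk_topic_run(c("a", "b"))
  run2 <- run1
  run2$score <- run2$score * 1e6 + 5
  for (f in list(function(r) precision_at_k(r, qrels, 2L),
                 function(r) ndcg_at_k(r, qrels, 2L),
                 function(r) average_precision(r, qrels),
                 function(r) bpref(r, qrels))) {
    expect_equal(f(run1), f(run2))
  }
})

test_that("the delimited report mirrors the evaluator layout", {
  qrels <- tibble::tibble(topic = 1L, doc_id = "a", grade = 2L)
  report <- evaluate_run(mk_topic_run(c("a", "b")), qrels, ks = 5L)
  path <- withr::local_tempfile()
  write_eval_report(report, path)
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  expect_true(all(lengths(parts) == 3L))
  expect_true(any(vapply(parts, function(p) p[2] == "all", logical(1))))
  expect_true(any(vapply(parts, function(p) p[1] == "map" && p[2] == "all",
                         logical(1))))
})

test_that("recency profile bins dated relevant documents", {
  corpus <- tiny_corpus()
  qrels <- tibble::tibble(topic = 1L, doc_id = c("a", "b", "c"),
                          grade = c(2L, 2L, 1L))
  prof <- recency_profile(qrels, corpus, min_grade = 2L, bin = "month")
  expect_equal(sum(prof$count), 2L)  # a and b are dated grade-2 docs
  one <- recency_profile(qrels[qrels$doc_id == "a", ], corpus, 2L, "week")
  expect_equal(nrow(one), 1L)
  expect_equal(one$count, 1L)
  # bin counts sum to the number of dated matching documents
  coll <- generate_collection(small_spec())
  prof2 <- recency_profile(coll$qrels, coll$corpus, min_grade = 2L)
  dated <- coll$corpus$publish_date[match(
    unique(coll$qrels$doc_id[coll$qrels$grade >= 2L]), coll$corpus$doc_id)]
  expect_equal(sum(prof2$count), sum(!is.na(dated)))
})
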