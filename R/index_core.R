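#' Build a field-aware inverted index
#'
#' Two index kinds mirror the two document representations used in the
#' study: the `"metadata"` index covers title and abstract; the
#' `"fulltext"` index folds the body text into the abstract section.
#' Each index carries three searchable sections: `"title"`,
#' `"abstract"` (abstract + full text for the full-text index) and
#' `"whole"` (all sections concatenated in order title, abstract, full
#' text).  Per section the index stores postings `term -> (doc, tf)`,
#' document lengths, the mean length, per-term document frequency and
#' collection frequency — the statistics consumed by the BM25, DFR and
#' LMD weighting formulas.
#'
#' @param corpus a corpus tibble (see [read_corpus()]).
#' @param kind `"metadata"` or `"fulltext"`.
#' @return an object of class `mr_index`.
#' @export
build_index <- function(corpus, kind = c("metadata", "fulltext")) {
  kind <- match.arg(kind)
  if (is.null(corpus) || nrow(corpus) == 0L) {
    abort_config("cannot build an index over an empty corpus")
  }
  if (anyDuplicated(corpus$doc_id)) abort_integrity("duplicate doc_id in corpus")
  title_toks <- tokenize_texts(corpus$title)
  abstract_toks <- tokenize_texts(corpus$abstract)
  if (kind == "fulltext") {
    ft_toks <- tokenize_texts(corpus$full_text)
    abstract_toks <- Map(c, abstract_toks, ft_toks)
  }
  whole_toks <- Map(c, title_toks, abstract_toks)
  fields <- list(
    title = field_from_tokens(title_toks),
    abstract = field_from_tokens(abstract_toks),
    whole = field_from_tokens(whole_toks)
  )
  structure(list(
    kind = kind,
    doc_ids = corpus$doc_id,
    dates = corpus$publish_date %||% rep(as.Date(NA), nrow(corpus)),
    fields = fields
  ), class = "mr_index")
}

# postings and statistics for one section, from per-doc token vectors
field_from_tokens <- function(toks) {
  doc_len <- lengths(toks)
  terms <- unlist(toks, use.names = FALSE)
  docs <- rep.int(seq_along(toks), doc_len)
  if (length(terms) > 0L) {
    cnt <- aggregate(list(tf = rep.int(1L, length(terms))),
                     by = list(term = terms, doc = docs), FUN = sum)
    cnt <- cnt[order(cnt$term, cnt$doc), ]
    postings <- lapply(split(cnt[, c("doc", "tf")], cnt$term),
                       function(p) list(doc = p$doc, tf = p$tf))
  } else {
    postings <- list()
  }
  cf <- vapply(postings, function(p) sum(p$tf), numeric(1))
  list(
    postings = postings,
    doc_len = as.integer(doc_len),
    n_docs = length(toks),
    avg_len = mean(doc_len),
    total_terms = sum(doc_len),
    df = lengths(lapply(postings, function(p) p$doc)),
    cf = cf
  )
}

#' @export
print.mr_index <- function(x, ...) {
  cat("<mr_index: ", x$kind, "> ", length(x$doc_ids), " documents, ",
      length(x$fields$whole$postings), " whole-document terms\n", sep = "")
  invisible(x)
}

#' Persist an index to disk
#'
#' The on-disk layout is a single JSON document with a versioned header
#' (`format`, `version`), the document ids and dates, and per-field
#' postings and statistics.  The layout is stable across minor versions
#' of the package; [load_index()] refuses other versions.
#'
#' @param index an `mr_index`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "mr_index"))
  payload <- list(
    format = "multiret-index",
    version = 1L,
    kind = index$kind,
    doc_ids = index$doc_ids,
    dates = ifelse(is.na(index$dates), "", format(index$dates, "%Y-%m-%d")),
    fields = lapply(index$fields, function(f) {
      list(doc_len = f$doc_len,
           postings = lapply(f$postings, function(p) list(doc = p$doc, tf = p$tf)))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an index persisted by [save_index()]
#'
#' @param path file path.
#' @return an `mr_index`.
#' @export
load_index <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such index file: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$format, "multiret-index") ||
      !identical(as.integer(payload$version), 1L)) {
    abort_format("unrecognized index format/version")
  }
  fields <- lapply(payload$fields, function(f) {
    postings <- lapply(f$postings, function(p)
      list(doc = as.integer(p$doc), tf = as.integer(p$tf)))
    doc_len <- as.integer(f$doc_len)
    list(postings = postings, doc_len = doc_len, n_docs = length(doc_len),
         avg_len = mean(doc_len), total_terms = sum(doc_len),
         df = lengths(lapply(postings, function(p) p$doc)),
         cf = vapply(postings, function(p) sum(p$tf), numeric(1)))
  })
  dates <- as.Date(ifelse(nzchar(payload$dates), payload$dates, NA))
  structure(list(kind = payload$kind, doc_ids = payload$doc_ids,
                 dates = dates, fields = fields), class = "mr_index")
}

#' Build the combinatorial query plan for a topic
#'
#' Each of the three topic fields (query, question, narrative) is
#' queried against both the title and the abstract section, and the
#' whole topic (query + question + narrative) against the whole
#' document — seven query specs per topic, whose per-document scores
#' are summed by [search_index()].  Synonym expansion, when a table is
#' given, is applied to each field's terms (queries only; documents are
#' indexed unexpanded).
#'
#' @param topic one row of a topics tibble.
#' @param index_kind `"metadata"` or `"fulltext"` (recorded on the plan;
#'   section names are identical for both kinds — the full-text index
#'   resolves its `"abstract"` section to abstract + body text).
#' @param synonyms an `mr_synonyms` table or `NULL`.
#' @return a list of 7 query specs (`topic`, `source`, `target`,
#'   `terms`), with class `mr_query_plan`.
#' @export
make_query_plan <- function(topic, index_kind = c("metadata", "fulltext"),
                            synonyms = NULL) {
  index_kind <- match.arg(index_kind)
  stopifnot(nrow(topic) == 1L)
  fld <- function(name) expand_terms(normalize_terms(topic[[name]]), synonyms)
  q <- fld("query"); qu <- fld("question"); na <- fld("narrative")
  specs <- list(
    list(source = "query", target = "title", terms = q),
    list(source = "query", target = "abstract", terms = q),
    list(source = "question", target = "title", terms = qu),
    list(source = "question", target = "abstract", terms = qu),
    list(source = "narrative", target = "title", terms = na),
    list(source = "narrative", target = "abstract", terms = na),
    list(source = "all", target = "whole", terms = c(q, qu, na))
  )
  specs <- lapply(specs, function(s) {
    s$topic <- topic$number
    s
  })
  structure(specs, class = "mr_query_plan", index_kind = index_kind)
}

# score one section for a bag of query terms; returns a dense numeric
# vector over all documents in the index
score_field <- function(index, field, terms, model) {
  fld <- index$fields[[field]]
  if (is.null(fld)) abort_config(paste0("unknown index section: ", field))
  n <- fld$n_docs
  scores <- numeric(n)
  if (length(terms) == 0L) return(scores)
  qtf <- table(terms)
  for (term in names(qtf)) {
    p <- fld$postings[[term]]
    mult <- as.numeric(qtf[[term]])
    if (model$name == "lmd") {
      cf <- if (is.null(p)) 0 else fld$cf[[term]]
      if (cf <= 0) next  # unseen everywhere: contributes nothing
      stats <- list(total_terms = fld$total_terms, cf = cf)
      base <- lmd_weight(rep(0, n), fld$doc_len, stats, model$params)
      if (!is.null(p)) {
        base[p$doc] <- lmd_weight(p$tf, fld$doc_len[p$doc], stats, model$params)
      }
      scores <- scores + mult * base
    } else {
      if (is.null(p)) next
      w <- if (model$name == "bm25") {
        stats <- list(n_docs = n, avg_len = fld$avg_len, df = fld$df[[term]])
        bm25_weight(p$tf, fld$doc_len[p$doc], stats, model$params)
      } else {
        stats <- list(n_docs = n, avg_len = fld$avg_len, cf = fld$cf[[term]])
        dfr_weight(p$tf, fld$doc_len[p$doc], stats, model$params)
      }
      scores[p$doc] <- scores[p$doc] + mult * w
    }
  }
  scores
}

#' Search an index with a topic's combinatorial query plan
#'
#' A document's score is the unweighted sum, over the seven query
#' specs, of the weighting model's query-document score on the spec's
#' target section.  Documents published strictly before `cutoff` are
#' excluded; undated documents are retained unless
#' `keep_undated = FALSE`.  Results are sorted by descending score with
#' ties broken by ascending `doc_id`, truncated to `top_k`; documents
#' whose total score is exactly zero are never returned.
#'
#' @param index an `mr_index`.
#' @param topic one row of a topics tibble, or an `mr_query_plan`.
#' @param model an `mr_model` (see [weighting_model()]).
#' @param top_k maximum number of results (>= 1).
#' @param cutoff optional `Date`; documents with `publish_date < cutoff`
#'   are excluded (the study used 2019-12-01).
#' @param keep_undated keep documents with no parseable date (default
#'   `TRUE`).
#' @param synonyms optional `mr_synonyms` query-expansion table.
#' @param tag run label for the result.
#' @return a run tibble for this topic.
#' @export
search_index <- function(index, topic, model, top_k = 1000L, cutoff = NULL,
                         keep_undated = TRUE, synonyms = NULL,
                         tag = model$name) {
  stopifnot(inherits(index, "mr_index"), top_k >= 1L)
  if (!inherits(model, "mr_model")) abort_config("unknown weighting model handle")
  plan <- if (inherits(topic, "mr_query_plan")) topic else {
    make_query_plan(topic, index$kind, synonyms)
  }
  total <- numeric(length(index$doc_ids))
  for (spec in plan) total <- total + score_field(index, spec$target, spec$terms, model)
  keep <- total != 0
  if (!is.null(cutoff)) {
    cutoff <- as.Date(cutoff)
    dated_out <- !is.na(index$dates) & index$dates < cutoff
    keep <- keep & !dated_out
    if (!keep_undated) keep <- keep & !is.na(index$dates)
  }
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble::tibble(topic = integer(), doc_id = character(),
                          rank = integer(), score = numeric(), tag = character()))
  }
  ord <- idx[order(-total[idx], index$doc_ids[idx])]
  ord <- head(ord, top_k)
  tibble::tibble(
    topic = plan[[1L]]$topic,
    doc_id = index$doc_ids[ord],
    rank = seq_along(ord),
    score = total[ord],
    tag = tag
  )
}

#' Search an index for every topic in a set
#'
#' @inheritParams search_index
#' @param topics a topics tibble.
#' @return a run tibble covering all topics.
#' @export
search_topics <- function(index, topics, model, top_k = 1000L, cutoff = NULL,
                          keep_undated = TRUE, synonyms = NULL,
                          tag = model$name) {
  runs <- lapply(seq_len(nrow(topics)), function(i) {
    search_index(index, topics[i, ], model, top_k = top_k, cutoff = cutoff,
                 keep_undated = keep_undated, synonyms = synonyms, tag = tag)
  })
  dplyr::bind_rows(runs)
}

#' Tune weighting-model parameters by cross-validated P@10
#'
#' Topics are split deterministically into `folds` folds by topic
#' number modulo `folds`; for every grid point the mean P@10 over the
#' held-out folds is computed, and the argmax is returned (ties broken
#' by grid order).  This mirrors tuning on the previous round's
#' relevance judgments in 5-fold cross-validation.
#'
#' @param index an `mr_index`.
#' @param topics a topics tibble.
#' @param qrels a qrels tibble.
#' @param model_name `"bm25"`, `"dfr"` or `"lmd"`.
#' @param grid a data frame of candidate parameter combinations (one
#'   column per parameter).
#' @param folds number of cross-validation folds (default 5).
#' @param k_eval precision cut-off being optimized (default 10).
#' @param top_k search depth per topic during tuning.
#' @param ... passed to [search_topics()] (`cutoff`, `synonyms`, ...).
#' @return a list with `best` (named list of parameters) and `scores`
#'   (the grid with a `mean_p10` column).
#' @export
fit_params <- function(index, topics, qrels, model_name, grid, folds = 5L,
                       k_eval = 10L, top_k = 1000L, ...) {
  if (is.null(grid) || nrow(grid) == 0L) abort_config("empty parameter grid")
  if (folds > nrow(topics)) abort_config("more folds than topics")
  judged_rel <- unique(qrels$topic[qrels$grade >= 1])
  if (sum(topics$number %in% judged_rel) < folds) {
    abort_config("need at least `folds` topics with a relevant judgment")
  }
  fold_id <- topics$number %% folds
  mean_p10 <- vapply(seq_len(nrow(grid)), function(g) {
    model <- do.call(weighting_model, c(list(name = model_name), as.list(grid[g, , drop = FALSE])))
    per_topic <- vapply(unique(fold_id), function(f) {
      held <- topics[fold_id == f, , drop = FALSE]
      run <- search_topics(index, held, model, top_k = top_k, ...)
      p <- vapply(held$number, function(tn) {
        precision_at_k(run[run$topic == tn, ], qrels, k = k_eval)
      }, numeric(1))
      sum(p)
    }, numeric(1))
    sum(per_topic) / nrow(topics)
  }, numeric(1))
  best <- which.max(mean_p10)  # first maximum wins ties
  list(best = as.list(grid[best, , drop = FALSE]),
       scores = tibble::as_tibble(cbind(grid, mean_p10 = mean_p10)))
}
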