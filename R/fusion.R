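#' Reciprocal rank fusion of ranked lists for one topic
#'
#' Each document's fused score is the sum, over the input lists that
#' contain it, of `1 / (k + rank)`.  Documents absent from a list
#' contribute nothing from it.  The threshold `k` defaults to 60, the
#' value tuned on earlier challenge rounds.
#'
#' @param lists a list of single-topic run tibbles sharing one topic
#'   number.
#' @param k positive RRF threshold (default 60).
#' @param tag run label for the fused list.
#' @return a fused single-topic run tibble, sorted by descending fused
#'   score with ties broken by ascending `doc_id`.
#' @export
rrf_fuse <- function(lists, k = 60, tag = "rrf") {
  stopifnot(is.list(lists), length(lists) >= 1L, k > 0)
  topics <- unique(unlist(lapply(lists, function(l) unique(l$topic))))
  if (length(topics) > 1L) {
    abort_integrity("rrf_fuse received lists with mixed topic numbers")
  }
  all_docs <- unlist(lapply(lists, function(l) l$doc_id), use.names = FALSE)
  contrib <- unlist(lapply(lists, function(l) 1 / (k + l$rank)), use.names = FALSE)
  if (length(all_docs) == 0L) {
    return(tibble::tibble(topic = integer(), doc_id = character(),
                          rank = integer(), score = numeric(), tag = character()))
  }
  fused <- tapply(contrib, all_docs, sum)
  as_run(rep(topics, length(fused)), names(fused), as.numeric(fused), tag = tag)
}

#' Reciprocal rank fusion of multi-topic runs
#'
#' Applies [rrf_fuse()] topic by topic over the union of topics covered
#' by the input runs.
#'
#' @param runs a list of run tibbles (possibly multi-topic).
#' @param k positive RRF threshold.
#' @param tag run label.
#' @return a fused run tibble over all topics.
#' @export
rrf_fuse_runs <- function(runs, k = 60, tag = "rrf") {
  stopifnot(length(runs) >= 1L)
  topics <- sort(unique(unlist(lapply(runs, function(r) unique(r$topic)))))
  fused <- lapply(topics, function(tn) {
    per_topic <- lapply(runs, function(r) r[r$topic == tn, , drop = FALSE])
    per_topic <- per_topic[vapply(per_topic, nrow, integer(1)) > 0L]
    rrf_fuse(per_topic, k = k, tag = tag)
  })
  dplyr::bind_rows(fused)
}

# --- second-stage scorer registry -------------------------------------

the_registry <- new.env(parent = emptyenv())
the_registry$scorers <- list()
the_registry$pairwise <- list()

#' Register a second-stage reranker
#'
#' A reranker satisfies the scorer contract: a deterministic function
#' `(topic_row, doc_row) -> finite numeric score`, total over any
#' (topic, document) pair.  Registered scorers are referenced by name
#' in pipeline configs; transformer-based rerankers can be adapters
#' satisfying this contract.
#'
#' @param name registry name.
#' @param fn the scorer function.
#' @return `name`, invisibly.
#' @export
register_scorer <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  the_registry$scorers[[name]] <- fn
  invisible(name)
}

#' Look up a registered scorer by name
#'
#' @param name registry name.
#' @return the scorer function; unknown names are a configuration error.
#' @export
get_scorer <- function(name) {
  fn <- the_registry$scorers[[name]]
  if (is.null(fn)) abort_config(paste0("no scorer registered under: ", name))
  fn
}

#' @rdname get_scorer
#' @export
list_scorers <- function() names(the_registry$scorers)

#' Register a pairwise learning-to-rank plug-in
#'
#' Slot for LambdaMART-style list-pair rankers: a function
#' `(features, qrels) -> run tibble`.  The package ships no
#' implementation; the recipe that uses it is only runnable once a
#' plug-in is registered.
#'
#' @param name registry name.
#' @param fn the ranker function.
#' @return `name`, invisibly.
#' @export
register_pairwise_ranker <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  the_registry$pairwise[[name]] <- fn
  invisible(name)
}

get_pairwise_ranker <- function(name) {
  fn <- the_registry$pairwise[[name]]
  if (is.null(fn)) {
    abort_config(paste0("no pairwise ranker registered under: ", name))
  }
  fn
}

#' Deterministic lexical-overlap scorer
#'
#' The shipped mock second-stage scorer: the fraction of the topic
#' field's normalized terms that occur in the document's title +
#' abstract.  Scores lie in `[0, 1]`; a topic field with no terms
#' scores 0.  Three instances (over the query, question and narrative
#' fields) are registered at package load under the names
#' `"overlap_query"`, `"overlap_question"`, `"overlap_narrative"` and
#' stand in for the masked-language-model ensemble in tests and
#' fixtures.
#'
#' @param field topic field to overlap: `"query"`, `"question"` or
#'   `"narrative"`.
#' @return a scorer function `(topic_row, doc_row) -> numeric`.
#' @export
make_overlap_scorer <- function(field = c("question", "query", "narrative")) {
  field <- match.arg(field)
  function(topic, doc) {
    terms <- unique(normalize_terms(topic[[field]]))
    if (length(terms) == 0L) return(0)
    doc_terms <- unique(c(normalize_terms(doc$title), normalize_terms(doc$abstract)))
    mean(terms %in% doc_terms)
  }
}

#' Rerank the top of a first-stage list with a second-stage scorer
#'
#' The top `min(k, length)` entries of each topic's list are rescored
#' by the scorer and re-sorted (descending score, ties by ascending
#' `doc_id`); entries beyond `k` are dropped.  The study reranked the
#' top 5000 first-stage documents with each masked language model.
#'
#' @param run a run tibble (first-stage results).
#' @param scorer a scorer function or a registered scorer name.
#' @param corpus the corpus tibble (document lookup; a doc_id missing
#'   from it is an integrity error).
#' @param topics the topics tibble.
#' @param k rerank depth (default 5000).
#' @param tag run label.
#' @return a run tibble with the scorer's scores.
#' @export
rerank_topk <- function(run, scorer, corpus, topics, k = 5000L, tag = "rerank") {
  stopifnot(k >= 1L)
  if (is.character(scorer)) scorer <- get_scorer(scorer)
  missing_docs <- setdiff(unique(run$doc_id), corpus$doc_id)
  if (length(missing_docs) > 0L) {
    abort_integrity(paste0("doc_id not in corpus: ",
                           paste(head(missing_docs, 5L), collapse = ", ")))
  }
  doc_row <- match(run$doc_id, corpus$doc_id)
  out <- lapply(sort(unique(run$topic)), function(tn) {
    topic <- topics[topics$number == tn, , drop = FALSE]
    if (nrow(topic) == 0L) {
      abort_integrity(paste0("topic ", tn, " not in topic set"))
    }
    sel <- which(run$topic == tn & run$rank <= k)
    scores <- vapply(sel, function(i) {
      scorer(topic, corpus[doc_row[i], , drop = FALSE])
    }, numeric(1))
    as_run(rep(tn, length(sel)), run$doc_id[sel], scores, tag = tag)
  })
  dplyr::bind_rows(out)
}
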