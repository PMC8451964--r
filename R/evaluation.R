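# Graded-relevance evaluation in the trec_eval conventions: binary
# relevance is grade >= 1; unjudged documents count as nonrelevant for
# P@K/AP, are excluded from the NDCG ideal pool, and are skipped in
# Bpref's ranked-above counts (condensed over judged documents only).

# grade lookup for one topic: named integer vector doc_id -> grade
topic_grades <- function(qrels, topic) {
  q <- qrels[qrels$topic == topic, , drop = FALSE]
  setNames(as.integer(q$grade), q$doc_id)
}

#' Precision at K
#'
#' Fraction of the top `K` ranked documents that are judged relevant
#' (grade >= 1); lists shorter than `K` are padded as nonrelevant, and
#' unjudged documents count as nonrelevant.
#'
#' @param run a single-topic run tibble.
#' @param qrels a qrels tibble.
#' @param k cut-off (>= 1).
#' @return a number in `[0, 1]`.
#' @export
precision_at_k <- function(run, qrels, k) {
  stopifnot(k >= 1L)
  tn <- unique(run$topic)
  if (length(tn) > 1L) abort_integrity("precision_at_k expects a single topic")
  if (length(tn) == 0L) return(0)
  grades <- topic_grades(qrels, tn)
  top <- run$doc_id[order(run$rank)][seq_len(min(k, nrow(run)))]
  rel <- !is.na(grades[top]) & grades[top] >= 1L
  sum(rel) / k
}

#' NDCG at K
#'
#' Discounted cumulative gain with raw graded gains (`0/1/2`) and the
#' `1 / log2(rank + 1)` discount, normalized by the ideal DCG computed
#' from all judged grades of the topic sorted descending (the
#' `ndcg_cut` convention of trec_eval); 0 when the topic has no judged
#' relevant document.
#'
#' @inheritParams precision_at_k
#' @return a number in `[0, 1]`.
#' @export
ndcg_at_k <- function(run, qrels, k) {
  stopifnot(k >= 1L)
  tn <- unique(run$topic)
  if (length(tn) > 1L) abort_integrity("ndcg_at_k expects a single topic")
  if (length(tn) == 0L) return(0)
  grades <- topic_grades(qrels, tn)
  top <- run$doc_id[order(run$rank)][seq_len(min(k, nrow(run)))]
  gain <- grades[top]
  gain[is.na(gain)] <- 0L
  dcg <- sum(gain / log2(seq_along(gain) + 1))
  ideal <- sort(grades, decreasing = TRUE)
  ideal <- ideal[seq_len(min(k, length(ideal)))]
  idcg <- sum(ideal / log2(seq_along(ideal) + 1))
  if (idcg == 0) 0 else dcg / idcg
}

#' Average precision
#'
#' `AP = (1/R) * sum over relevant retrieved at rank i of
#' (relevant in top i) / i`, with `R` the number of judged-relevant
#' documents for the topic; 0 (with a warning) when `R = 0`.
#'
#' @inheritParams precision_at_k
#' @return a number in `[0, 1]`.
#' @export
average_precision <- function(run, qrels) {
  tn <- unique(run$topic)
  if (length(tn) > 1L) abort_integrity("average_precision expects a single topic")
  grades <- if (length(tn) == 1L) topic_grades(qrels, tn) else integer()
  R <- sum(grades >= 1L)
  if (R == 0L) {
    warning("topic has no judged relevant documents; AP = 0")
    return(0)
  }
  docs <- run$doc_id[order(run$rank)]
  rel <- !is.na(grades[docs]) & grades[docs] >= 1L
  if (!any(rel)) return(0)
  sum(cumsum(rel)[rel] / which(rel)) / R
}

#' Binary preference (Bpref)
#'
#' How often judged-relevant documents are ranked above judged-
#' nonrelevant ones, robust to unjudged documents:
#' `Bpref = (1/R) * sum over relevant retrieved r of
#' (1 - min(nonrel ranked above r, R) / min(R, N))` with `R` judged
#' relevant and `N` judged nonrelevant for the topic.  Unjudged
#' documents never enter the ranked-above count.
#'
#' @inheritParams precision_at_k
#' @return a number in `[0, 1]`.
#' @export
bpref <- function(run, qrels) {
  tn <- unique(run$topic)
  if (length(tn) > 1L) abort_integrity("bpref expects a single topic")
  grades <- if (length(tn) == 1L) topic_grades(qrels, tn) else integer()
  R <- sum(grades >= 1L)
  N <- sum(grades == 0L)
  if (R == 0L) {
    warning("topic has no judged relevant documents; Bpref = 0")
    return(0)
  }
  docs <- run$doc_id[order(run$rank)]
  judged <- docs[docs %in% names(grades)]
  rel <- grades[judged] >= 1L
  if (N == 0L) return(sum(rel) / R)  # no nonrelevant judged: full credit per rel retrieved
  nonrel_above <- cumsum(!rel)
  sum(1 - pmin(nonrel_above[rel], R) / min(R, N)) / R
}

#' Evaluate a run against graded judgments
#'
#' Computes P@K and NDCG@K for each requested cut-off, plus MAP and
#' Bpref, per topic and macro-averaged over the topics that have at
#' least one judgment (the trec_eval convention).  Topics present in
#' the run but absent from the qrels are skipped.
#'
#' @param run a run tibble (any number of topics).
#' @param qrels a qrels tibble.
#' @param ks integer vector of cut-offs (default `c(5, 10, 20)`).
#' @return an object of class `mr_metrics`: a list with `per_topic`
#'   (tibble with one row per evaluated topic: `p_at_<k>`,
#'   `ndcg_at_<k>`, `ap`, `bpref`, `num_rel`, `num_rel_ret`) and
#'   `summary` (named numeric of macro averages, with `map` for mean
#'   AP).
#' @export
evaluate_run <- function(run, qrels, ks = c(5L, 10L, 20L)) {
  topics <- intersect(unique(run$topic), unique(qrels$topic))
  if (length(topics) == 0L) {
    abort_integrity("no topics in common between run and qrels")
  }
  rows <- lapply(sort(topics), function(tn) {
    sub <- run[run$topic == tn, , drop = FALSE]
    grades <- topic_grades(qrels, tn)
    row <- list(topic = tn)
    for (k in ks) {
      row[[paste0("p_at_", k)]] <- precision_at_k(sub, qrels, k)
      row[[paste0("ndcg_at_", k)]] <- ndcg_at_k(sub, qrels, k)
    }
    row$ap <- suppressWarnings(average_precision(sub, qrels))
    row$bpref <- suppressWarnings(bpref(sub, qrels))
    row$num_rel <- sum(grades >= 1L)
    row$num_rel_ret <- sum(sub$doc_id %in% names(grades)[grades >= 1L])
    tibble::as_tibble(row)
  })
  per_topic <- dplyr::bind_rows(rows)
  metric_cols <- setdiff(names(per_topic), "topic")
  summary <- vapply(per_topic[metric_cols], mean, numeric(1))
  names(summary)[names(summary) == "ap"] <- "map"
  structure(list(per_topic = per_topic, summary = summary, ks = ks),
            class = "mr_metrics")
}

#' @export
print.mr_metrics <- function(x, ...) {
  cat("<mr_metrics> ", nrow(x$per_topic), " topic(s)\n", sep = "")
  print(round(x$summary, 4))
  invisible(x)
}

#' Write a metrics report as delimited text
#'
#' One `metric <tab> topic <tab> value` line per cell, with the macro
#' averages keyed by topic `all` — mirroring the reference evaluator's
#' layout for diffability.
#'
#' @param report an `mr_metrics` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "mr_metrics"))
  lines <- character()
  for (i in seq_len(nrow(report$per_topic))) {
    row <- report$per_topic[i, ]
    for (m in setdiff(names(row), "topic")) {
      lines <- c(lines, sprintf("%s\t%d\t%.6f", m, row$topic, row[[m]]))
    }
  }
  for (m in names(report$summary)) {
    lines <- c(lines, sprintf("%s\tall\t%.6f", m, report$summary[[m]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Publication-date profile of judged-relevant documents
#'
#' Histogram of the publication dates of the judged documents at or
#' above a grade threshold, binned by week or month; documents without
#' a parseable date are dropped.  Reproduces the relevance-by-recency
#' view that motivates date filtering in a fast-moving corpus.
#'
#' @param qrels a qrels tibble.
#' @param corpus a corpus tibble.
#' @param min_grade minimum grade to count (default 2, "highly
#'   relevant").
#' @param bin `"week"` or `"month"`.
#' @return a tibble with `bin_start` (`Date`) and `count`; counts sum
#'   to the number of dated documents matching the filter.
#' @export
recency_profile <- function(qrels, corpus, min_grade = 2L,
                            bin = c("week", "month")) {
  bin <- match.arg(bin)
  docs <- unique(qrels$doc_id[qrels$grade >= min_grade])
  dates <- corpus$publish_date[match(docs, corpus$doc_id)]
  dates <- dates[!is.na(dates)]
  if (length(dates) == 0L) {
    return(tibble::tibble(bin_start = as.Date(character()), count = integer()))
  }
  starts <- as.Date(cut(dates, breaks = bin))
  tab <- table(starts)
  tibble::tibble(bin_start = as.Date(names(tab)), count = as.integer(tab))
}
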