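# Independent oracles, deliberately written as naive loops over
# materialized tables -- a separate code path from the package's
# vectorized implementations.

# ---- retrieval scoring: direct application of the weighting formulas
# to raw token lists, no inverted index -------------------------------

oracle_term_weight <- function(model_name, params, tf, doc_len, n_docs,
                               avg_len, df, cf, total_terms) {
  if (model_name == "bm25") {
    if (tf == 0) return(0)
    idf <- log(1 + (n_docs - df + 0.5) / (df + 0.5))
    return(idf * tf * (params$k1 + 1) /
             (tf + params$k1 * (1 - params$b + params$b * doc_len / avg_len)))
  }
  if (model_name == "dfr") {
    if (tf == 0) return(0)
    lambda <- cf / n_docs
    tfn <- tf * log2(1 + avg_len / doc_len)
    return(params$k * (-log2(1 / (1 + lambda)) - tfn * log2(lambda / (1 + lambda))))
  }
  # lmd: every document gets a smoothed score for terms seen in the collection
  p_coll <- cf / total_terms
  log((tf + params$mu * p_coll) / (doc_len + params$mu))
}

# score every document of `sections` (list field -> list of per-doc token
# vectors) for a bag of query terms against one field
oracle_score_field <- function(sections, field, terms, model_name, params) {
  toks <- sections[[field]]
  n_docs <- length(toks)
  lens <- vapply(toks, length, integer(1))
  avg_len <- mean(lens)
  total_terms <- sum(lens)
  scores <- numeric(n_docs)
  for (term in terms) {
    df <- sum(vapply(toks, function(t) term %in% t, logical(1)))
    cf <- sum(vapply(toks, function(t) sum(t == term), numeric(1)))
    if (model_name == "lmd" && cf == 0) next
    for (d in seq_len(n_docs)) {
      tf <- sum(toks[[d]] == term)
      if (model_name != "lmd" && tf == 0) next
      scores[d] <- scores[d] + oracle_term_weight(
        model_name, params, tf, lens[d], n_docs, avg_len, df, cf, total_terms)
    }
  }
  scores
}

# document sections for an index kind, from a corpus tibble
oracle_sections <- function(corpus, kind) {
  title <- lapply(corpus$title, normalize_terms)
  abstract <- lapply(corpus$abstract, normalize_terms)
  if (kind == "fulltext") {
    ft <- lapply(corpus$full_text, function(x) {
      if (is.na(x)) character() else normalize_terms(x)
    })
    abstract <- Map(c, abstract, ft)
  }
  list(title = title, abstract = abstract, whole = Map(c, title, abstract))
}

# total score per document under the 7-query combinatorial plan
oracle_search_scores <- function(corpus, topic, model_name, params,
                                 kind = "metadata", synonyms = NULL) {
  sections <- oracle_sections(corpus, kind)
  f <- function(name) expand_terms(normalize_terms(topic[[name]]), synonyms)
  q <- f("query"); qu <- f("question"); na <- f("narrative")
  specs <- list(list(q, "title"), list(q, "abstract"),
                list(qu, "title"), list(qu, "abstract"),
                list(na, "title"), list(na, "abstract"),
                list(c(q, qu, na), "whole"))
  total <- numeric(nrow(corpus))
  for (s in specs) {
    total <- total + oracle_score_field(sections, s[[2]], s[[1]], model_name, params)
  }
  names(total) <- corpus$doc_id
  total
}

# ---- graded-relevance metrics, loop style ---------------------------

oracle_p_at_k <- function(docs_in_rank_order, grades, k) {
  hits <- 0
  for (i in seq_len(min(k, length(docs_in_rank_order)))) {
    g <- grades[[docs_in_rank_order[i]]]
    if (!is.null(g) && !is.na(g) && g >= 1) hits <- hits + 1
  }
  hits / k
}

oracle_ndcg_at_k <- function(docs_in_rank_order, grades, k) {
  dcg <- 0
  for (i in seq_len(min(k, length(docs_in_rank_order)))) {
    g <- grades[[docs_in_rank_order[i]]]
    if (!is.null(g) && !is.na(g)) dcg <- dcg + g / log2(i + 1)
  }
  ideal <- unname(sort(unlist(grades), decreasing = TRUE))
  idcg <- 0
  for (i in seq_len(min(k, length(ideal)))) idcg <- idcg + ideal[i] / log2(i + 1)
  if (idcg == 0) 0 else dcg / idcg
}

oracle_ap <- function(docs_in_rank_order, grades) {
  R <- sum(unlist(grades) >= 1)
  if (R == 0) return(0)
  rel_seen <- 0
  total <- 0
  for (i in seq_along(docs_in_rank_order)) {
    g <- grades[[docs_in_rank_order[i]]]
    if (!is.null(g) && !is.na(g) && g >= 1) {
      rel_seen <- rel_seen + 1
      total <- total + rel_seen / i
    }
  }
  total / R
}

oracle_bpref <- function(docs_in_rank_order, grades) {
  R <- sum(unlist(grades) >= 1)
  N <- sum(unlist(grades) == 0)
  if (R == 0) return(0)
  nonrel_above <- 0
  total <- 0
  for (d in docs_in_rank_order) {
    g <- grades[[d]]
    if (is.null(g) || is.na(g)) next
    if (g >= 1) {
      total <- total + if (N == 0) 1 else 1 - min(nonrel_above, R) / min(R, N)
    } else {
      nonrel_above <- nonrel_above + 1
    }
  }
  total / R
}

# grades for one topic as a named list doc_id -> grade
oracle_grades <- function(qrels, tn) {
  q <- qrels[qrels$topic == tn, ]
  out <- as.list(as.integer(q$grade))
  names(out) <- q$doc_id
  out
}

# ---- reciprocal rank fusion by materializing the score table --------

oracle_rrf <- function(lists, k) {
  docs <- unique(unlist(lapply(lists, function(l) l$doc_id)))
  table <- matrix(0, nrow = length(docs), ncol = length(lists),
                  dimnames = list(docs, NULL))
  for (j in seq_along(lists)) {
    l <- lists[[j]]
    for (i in seq_len(nrow(l))) {
      table[l$doc_id[i], j] <- 1 / (k + l$rank[i])
    }
  }
  rowSums(table)
}

# ---- reference logistic optimizer (BFGS on the identical penalized
# negative log-likelihood over standardized features) -----------------

reference_logistic_loss <- function(features, feat_names, l2) {
  train <- features[!is.na(features$label), , drop = FALSE]
  y <- as.numeric(train$label)
  x <- as.matrix(train[, feat_names, drop = FALSE])
  centers <- colMeans(x)
  scales <- apply(x, 2, stats::sd)
  scales[scales == 0 | is.na(scales)] <- 1
  z <- sweep(sweep(x, 2, centers), 2, scales, "/")
  design <- cbind(1, z)
  pen <- c(0, rep(l2, ncol(z)))
  nll <- function(beta) {
    eta <- drop(design %*% beta)
    ld <- ifelse(eta > 30, eta, log1p(exp(eta)))
    -sum(y * eta - ld) + sum(pen * beta^2) / 2
  }
  fit <- stats::optim(numeric(ncol(design)), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  fit$value
}
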