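#' First-stage weighting model handle
#'
#' Binds one of the three probabilistic bag-of-words models to its
#' parameters.  Defaults are the untuned values used before any
#' relevance judgments are available: `k1 = 1.2`, `b = 0.75` for BM25,
#' `mu = 2000` for the Dirichlet language model, and `k = 1` with the
#' geometric randomness model for DFR.
#'
#' @param name `"bm25"`, `"dfr"` or `"lmd"`.
#' @param ... parameter overrides: `k1`, `b` (BM25); `k`, `randomness`
#'   (`"geometric"` or `"poisson"`; DFR); `mu` (LMD).
#' @return a list with class `mr_model` holding `name` and `params`.
#' @export
weighting_model <- function(name = c("bm25", "dfr", "lmd"), ...) {
  name <- match.arg(name)
  dots <- list(...)
  params <- switch(name,
    bm25 = list(k1 = 1.2, b = 0.75),
    dfr = list(k = 1, randomness = "geometric"),
    lmd = list(mu = 2000)
  )
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown) > 0L) {
    abort_config(paste0("unknown ", name, " parameter(s): ",
                        paste(unknown, collapse = ", ")))
  }
  params[names(dots)] <- dots
  if (name == "bm25" && (params$b < 0 || params$b > 1 || params$k1 < 0)) {
    abort_config("BM25 requires 0 <= b <= 1 and k1 >= 0")
  }
  if (name == "dfr" && (!params$randomness %in% c("geometric", "poisson") ||
                        params$k <= 0)) {
    abort_config("DFR requires k > 0 and a geometric or poisson randomness model")
  }
  if (name == "lmd" && params$mu <= 0) abort_config("LMD requires mu > 0")
  structure(list(name = name, params = params), class = "mr_model")
}

#' @export
print.mr_model <- function(x, ...) {
  cat("<", x$name, " weighting model> ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Okapi BM25 term weight
#'
#' `idf(t) * tf * (k1 + 1) / (tf + k1 * (1 - b + b * |d| / avg_l))` with
#' the nonnegative (Lucene-style) inverse document frequency
#' `idf = ln(1 + (|D| - n_t + 0.5) / (n_t + 0.5))`.  Zero when `tf = 0`.
#'
#' @param tf term frequency `f(t, d)` (vectorized).
#' @param doc_len document length `|d|` in terms (vectorized with `tf`).
#' @param stats list with `n_docs` (collection size `|D|`), `avg_len`
#'   (mean document length), `df` (document frequency `n_t`).
#' @param params a `BM25` parameter list (`k1`, `b`), e.g.
#'   `weighting_model("bm25")$params`.
#' @return numeric vector of term weights.
#' @export
bm25_weight <- function(tf, doc_len, stats, params = weighting_model("bm25")$params) {
  if (stats$avg_len <= 0) abort_config("invalid statistics: avg_len <= 0")
  idf <- log(1 + (stats$n_docs - stats$df + 0.5) / (stats$df + 0.5))
  denom <- tf + params$k1 * (1 - params$b + params$b * doc_len / stats$avg_len)
  w <- idf * tf * (params$k1 + 1) / denom
  w[tf == 0] <- 0
  w
}

#' Divergence-from-randomness term weight
#'
#' Information content of the length-normalized term frequency under a
#' randomness model with mean `lambda = cf / |D|`.  The normalized
#' frequency is `tfn = tf * log2(1 + avg_len / |d|)`.  With the
#' geometric (Bose-Einstein) model the weight is
#' `k * (log2(1 + lambda) + tfn * log2((1 + lambda) / lambda))`;
#' with the Poisson model it is
#' `k * (lambda * log2(e) - tfn * log2(lambda) + log2(tfn!))`.
#' Zero when `tf = 0`.
#'
#' @param tf term frequency (vectorized).
#' @param doc_len document length (vectorized with `tf`).
#' @param stats list with `n_docs`, `avg_len`, `cf` (collection
#'   frequency of the term).
#' @param params DFR parameter list (`k`, `randomness`).
#' @return numeric vector of term weights.
#' @export
dfr_weight <- function(tf, doc_len, stats, params = weighting_model("dfr")$params) {
  if (stats$cf <= 0 && any(tf > 0)) {
    abort_config("invalid statistics: cf = 0 with tf > 0")
  }
  if (stats$cf <= 0) return(rep(0, length(tf)))
  lambda <- stats$cf / stats$n_docs
  tfn <- tf * log2(1 + stats$avg_len / doc_len)
  w <- if (identical(params$randomness, "poisson")) {
    params$k * (lambda * log2(exp(1)) - tfn * log2(lambda) +
                  lgamma(tfn + 1) / log(2))
  } else {
    params$k * (log2(1 + lambda) + tfn * log2((1 + lambda) / lambda))
  }
  w[tf == 0] <- 0
  w
}

#' Dirichlet-smoothed language-model term weight
#'
#' Per-term query log-likelihood
#' `ln((tf + mu * p(t|D)) / (|d| + mu))` with the collection model
#' `p(t|D) = cf / total collection terms`.  Terms absent from the whole
#' collection (`cf = 0`) are skipped by callers (they contribute 0);
#' calling this with `cf = 0` is an error.
#'
#' @param tf term frequency (vectorized).
#' @param doc_len document length (vectorized with `tf`).
#' @param stats list with `total_terms` (collection term count) and `cf`.
#' @param params LMD parameter list (`mu`).
#' @return numeric vector of (negative) log-probabilities.
#' @export
lmd_weight <- function(tf, doc_len, stats, params = weighting_model("lmd")$params) {
  if (stats$total_terms <= 0) abort_config("invalid statistics: empty collection")
  if (stats$cf <= 0) abort_config("lmd_weight requires cf > 0 (skip unseen terms)")
  p_coll <- stats$cf / stats$total_terms
  log((tf + params$mu * p_coll) / (doc_len + params$mu))
}
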