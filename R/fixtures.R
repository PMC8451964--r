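#' Specification of a synthetic literature collection
#'
#' Defines the deterministic generator used to exercise every stage of
#' the pipeline without any external download.  Documents are bags of
#' synthetic terms drawn from a mixture of a Zipf-distributed
#' background vocabulary and a per-theme signature distribution; each
#' latent theme yields one three-field topic whose relevance judgments
#' follow the generator's own overlap rule (see
#' [generate_collection()]).  The defaults are a desk-scale analogue of
#' the study conditions: a heterogeneous corpus (half the documents
#' with full text, a few percent with no parseable date), publication
#' dates concentrated near the collection snapshot with an exponential
#' tail reaching back before the outbreak-start cutoff, and roughly 25
#' graded judgments per topic.
#'
#' @param seed RNG seed; generation is a pure function of the spec.
#' @param vocab_size number of distinct terms.
#' @param n_themes number of latent themes (= topics).
#' @param docs_per_theme documents generated per theme.
#' @param signature_size signature terms per theme (disjoint across
#'   themes).
#' @param title_len,abstract_len,fulltext_len integer ranges
#'   `c(min, max)` of section lengths in terms.
#' @param fulltext_fraction fraction of documents carrying full text.
#' @param background_weight mixture weight of the Zipf background when
#'   sampling theme documents.
#' @param date_range character or `Date` vector `c(first, last)` of
#'   publication dates.
#' @param missing_date_fraction fraction of documents with no date.
#' @param grade2_overlap,grade1_overlap signature-overlap fractions at
#'   or above which a same-theme document is judged highly relevant
#'   (grade 2) or somewhat relevant (grade 1).
#' @param judged_nonrel_per_topic cross-theme documents judged
#'   irrelevant (grade 0) per topic.
#' @return a list with class `mr_synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 42L,
                           vocab_size = 500L,
                           n_themes = 10L,
                           docs_per_theme = 20L,
                           signature_size = 6L,
                           title_len = c(4L, 8L),
                           abstract_len = c(30L, 60L),
                           fulltext_len = c(150L, 300L),
                           fulltext_fraction = 0.5,
                           background_weight = 0.3,
                           date_range = c("2019-10-01", "2020-07-31"),
                           missing_date_fraction = 0.05,
                           grade2_overlap = 0.75,
                           grade1_overlap = 0.25,
                           judged_nonrel_per_topic = 8L) {
  spec <- list(seed = as.integer(seed), vocab_size = as.integer(vocab_size),
               n_themes = as.integer(n_themes),
               docs_per_theme = as.integer(docs_per_theme),
               signature_size = as.integer(signature_size),
               title_len = as.integer(title_len),
               abstract_len = as.integer(abstract_len),
               fulltext_len = as.integer(fulltext_len),
               fulltext_fraction = fulltext_fraction,
               background_weight = background_weight,
               date_range = as.Date(date_range),
               missing_date_fraction = missing_date_fraction,
               grade2_overlap = grade2_overlap,
               grade1_overlap = grade1_overlap,
               judged_nonrel_per_topic = as.integer(judged_nonrel_per_topic))
  if (any(unlist(spec[c("vocab_size", "n_themes", "docs_per_theme",
                        "signature_size")]) <= 0L)) {
    abort_config("all synthetic counts must be positive")
  }
  fracs <- c(spec$fulltext_fraction, spec$background_weight,
             spec$missing_date_fraction, spec$grade2_overlap, spec$grade1_overlap)
  if (any(fracs < 0 | fracs > 1)) abort_config("fractions must lie in [0, 1]")
  if (spec$n_themes * spec$signature_size > spec$vocab_size) {
    abort_config("theme signatures exceed the vocabulary")
  }
  structure(spec, class = "mr_synthetic_spec")
}

# run code under a fixed seed without disturbing the caller's RNG state
with_fixed_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# synthetic vocabulary: pronounceable-ish CVCV stems with a numeric
# suffix, so tokens survive normalization unchanged (the stemmer leaves
# tokens containing digits alone) and stay unique
make_vocab <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  stem <- paste0(sample(cons, n, replace = TRUE), sample(vow, n, replace = TRUE),
                 sample(cons, n, replace = TRUE), sample(vow, n, replace = TRUE))
  paste0(stem, seq_len(n))
}

#' Generate a deterministic synthetic collection
#'
#' Produces a corpus, a topic set and graded judgments that are a pure
#' function of the spec.  Each theme contributes `docs_per_theme`
#' documents: a few "core" documents embed the theme's full signature
#' in the abstract, a few "partial" documents embed part of it, and the
#' rest draw from the theme mixture.  Topic fields phrase the signature
#' (query: 2 terms; question: 4; narrative: all, with filler).  The
#' judgment rule is the generator's own: a same-theme document is
#' graded by its measured signature overlap in title + abstract (grade
#' 2 at or above `grade2_overlap`, grade 1 at or above
#' `grade1_overlap`, else 0), and a fixed number of cross-theme
#' documents per topic are judged irrelevant.  Every topic is
#' guaranteed at least one grade-2 and one grade-0 judgment.
#'
#' @param spec an [synthetic_spec()] object.
#' @return a list with `corpus`, `topics`, `qrels` tibbles and
#'   `signatures` (per-theme signature term sets).
#' @export
generate_collection <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "mr_synthetic_spec"))
  with_fixed_seed(spec$seed, {
    vocab <- make_vocab(spec$vocab_size)
    zipf <- (1 / seq_len(spec$vocab_size))
    zipf <- zipf / sum(zipf)
    sig_pool <- sample(spec$vocab_size, spec$n_themes * spec$signature_size)
    signatures <- split(vocab[sig_pool],
                        rep(seq_len(spec$n_themes), each = spec$signature_size))
    n_docs <- spec$n_themes * spec$docs_per_theme
    theme_of <- rep(seq_len(spec$n_themes), each = spec$docs_per_theme)
    # document archetypes per theme: 3 core, 4 partial, rest mixture
    archetype <- rep(rep(c("core", "partial", "plain"),
                         c(3L, 4L, spec$docs_per_theme - 7L)),
                     spec$n_themes)
    # core/partial documents draw theme terms densely; "plain" documents
    # only brush the theme, so their measured overlap (and hence grade)
    # varies across the 0/1/2 range
    theme_draw <- function(theme, n, sig_weight) {
      from_sig <- runif(n) < sig_weight
      terms <- character(n)
      terms[!from_sig] <- sample(vocab, sum(!from_sig), replace = TRUE, prob = zipf)
      terms[from_sig] <- sample(signatures[[theme]], sum(from_sig), replace = TRUE)
      terms
    }
    rlen <- function(range) sample(range[1L]:range[2L], 1L)
    docs <- lapply(seq_len(n_docs), function(i) {
      th <- theme_of[i]
      sig <- signatures[[th]]
      planted <- switch(archetype[i],
                        core = sig,
                        partial = sig[seq_len(ceiling(length(sig) / 3))],
                        plain = character())
      sig_weight <- if (archetype[i] == "plain") 0.08 else 1 - spec$background_weight
      title <- c(sig[1:2][archetype[i] != "plain"],
                 theme_draw(th, rlen(spec$title_len), sig_weight))
      abstract <- c(planted, theme_draw(th, rlen(spec$abstract_len), sig_weight))
      full_text <- if (runif(1) < spec$fulltext_fraction) {
        paste(theme_draw(th, rlen(spec$fulltext_len), sig_weight), collapse = " ")
      } else {
        NA_character_
      }
      list(title = paste(title, collapse = " "),
           abstract = paste(abstract, collapse = " "),
           full_text = full_text)
    })
    # dates: exponential lag back from the snapshot date, so relevance
    # concentrates near the most recent publications
    span <- as.numeric(spec$date_range[2L] - spec$date_range[1L])
    lag <- rexp(n_docs, rate = 4 / span)
    lag <- pmin(lag, span)
    dates <- spec$date_range[2L] - round(lag)
    dates[runif(n_docs) < spec$missing_date_fraction] <- NA
    corpus <- tibble::tibble(
      doc_id = sprintf("d%04d", seq_len(n_docs)),
      title = vapply(docs, `[[`, character(1), "title"),
      abstract = vapply(docs, `[[`, character(1), "abstract"),
      full_text = vapply(docs, `[[`, character(1), "full_text"),
      publish_date = dates,
      source = sample(c("medline", "pmc", "who", "biorxiv", "arxiv"),
                      n_docs, replace = TRUE, prob = c(0.4, 0.3, 0.1, 0.1, 0.1))
    )
    topics <- tibble::tibble(
      number = seq_len(spec$n_themes),
      query = vapply(signatures, function(s) paste(s[1:2], collapse = " "),
                     character(1)),
      question = vapply(signatures, function(s) {
        paste("What is known about", paste(s[1:4], collapse = " "))
      }, character(1)),
      narrative = vapply(signatures, function(s) {
        paste("Looking for studies discussing", paste(s, collapse = " "),
              "and related evidence")
      }, character(1))
    )
    qrels <- generate_qrels(spec, corpus, topics, signatures, theme_of)
    list(corpus = corpus, topics = topics, qrels = qrels,
         signatures = signatures)
  })
}

# the generative relevance rule: same-theme documents graded by
# signature overlap in title + abstract; sampled cross-theme documents
# judged irrelevant
generate_qrels <- function(spec, corpus, topics, signatures, theme_of) {
  doc_terms <- Map(c, tokenize_texts(corpus$title), tokenize_texts(corpus$abstract))
  rows <- lapply(seq_len(spec$n_themes), function(th) {
    sig <- signatures[[th]]
    same <- which(theme_of == th)
    overlap <- vapply(same, function(i) mean(sig %in% doc_terms[[i]]), numeric(1))
    grade <- ifelse(overlap >= spec$grade2_overlap, 2L,
                    ifelse(overlap >= spec$grade1_overlap, 1L, 0L))
    other <- which(theme_of != th)
    nonrel <- sort(sample(other, min(spec$judged_nonrel_per_topic, length(other))))
    tibble::tibble(
      topic = th,
      doc_id = corpus$doc_id[c(same, nonrel)],
      grade = c(grade, rep(0L, length(nonrel)))
    )
  })
  qrels <- dplyr::bind_rows(rows)
  per_topic <- split(qrels$grade, qrels$topic)
  ok <- vapply(per_topic, function(g) any(g == 2L) && any(g == 0L), logical(1))
  if (!all(ok)) {
    abort_config("infeasible spec: a topic lacks a grade-2 or grade-0 judgment")
  }
  qrels
}

#' Construct a complementary pair of runs for fusion testing
#'
#' Builds, from a generated collection, two synthetic runs whose top-3
#' sets are disjoint for every topic while each still contains relevant
#' documents: run A ranks (rel, nonrel, rel) and hides two further
#' relevant documents at ranks 4-5; run B leads with those two (and a
#' different nonrelevant document) and hides A's.  Reciprocal rank
#' fusion therefore lifts the four relevant documents above both
#' planted nonrelevant ones, so fused P@3 is at least each input's P@3
#' on every topic — the constructed analogue of fusing rankers that
#' retrieve disjoint but relevant top documents.
#'
#' @param collection a list from [generate_collection()] (needs at
#'   least 2 themes, 4 relevant and 2 judged-nonrelevant documents per
#'   topic).
#' @return a list with run tibbles `run_a` and `run_b`.
#' @export
adversarial_pair <- function(collection) {
  qrels <- collection$qrels
  if (length(unique(qrels$topic)) < 2L) {
    abort_config("adversarial_pair needs at least 2 themes")
  }
  build <- function(tn) {
    q <- qrels[qrels$topic == tn, , drop = FALSE]
    rel <- sort(q$doc_id[q$grade >= 1L])
    nonrel <- sort(q$doc_id[q$grade == 0L])
    if (length(rel) < 4L || length(nonrel) < 2L) {
      abort_config(paste0("topic ", tn, " lacks documents for the construction"))
    }
    a_docs <- c(rel[1L], nonrel[1L], rel[2L], rel[3L], rel[4L])
    b_docs <- c(rel[3L], nonrel[2L], rel[4L], rel[1L], rel[2L])
    list(
      a = tibble::tibble(topic = tn, doc_id = a_docs,
                         rank = 1:5, score = 1 / (1:5), tag = "adv-a"),
      b = tibble::tibble(topic = tn, doc_id = b_docs,
                         rank = 1:5, score = 1 / (1:5), tag = "adv-b")
    )
  }
  built <- lapply(sort(unique(qrels$topic)), build)
  list(run_a = validate_run(dplyr::bind_rows(lapply(built, `[[`, "a"))),
       run_b = validate_run(dplyr::bind_rows(lapply(built, `[[`, "b"))))
}
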