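#' Normalize raw text into index/search terms
#'
#' Deterministic normalization applied identically at indexing and at
#' search time: lower-case, replace every character outside
#' `[a-z0-9-]` with whitespace, split on whitespace, drop empty and
#' hyphen-only tokens, then Porter-stem each token.
#'
#' @param text a character scalar (empty string allowed; `NA` treated as
#'   empty).
#' @param stem apply the Porter stemmer (default `TRUE`).
#' @return character vector of normalized terms (possibly empty).
#' @examples
#' normalize_terms("Coronavirus origin")   # "coronaviru" "origin"
#' normalize_terms("SARS-CoV-2!!")         # "sars-cov-2"
#' @export
normalize_terms <- function(text, stem = TRUE) {
  if (length(text) == 0L || is.na(text)) return(character())
  stopifnot(length(text) == 1L)
  x <- tolower(text)
  x <- gsub("[^a-z0-9-]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- toks[nzchar(toks) & !grepl("^-+$", toks)]
  if (length(toks) == 0L) return(character())
  if (stem) porter_stem(toks) else toks
}

# normalize many texts at once; returns a list of term vectors, with
# stemming done once per distinct token (the hot path of index building)
tokenize_texts <- function(texts, stem = TRUE) {
  texts[is.na(texts)] <- ""
  x <- tolower(texts)
  x <- gsub("[^a-z0-9-]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")
  toks <- lapply(toks, function(t) t[nzchar(t) & !grepl("^-+$", t)])
  if (!stem) return(toks)
  flat <- unlist(toks, use.names = FALSE)
  if (length(flat) == 0L) return(toks)
  uniq <- unique(flat)
  stems <- setNames(porter_stem(uniq), uniq)
  lens <- lengths(toks)
  stemmed <- unname(stems[flat])
  split_idx <- rep.int(seq_along(toks), lens)
  out <- rep(list(character()), length(toks))
  got <- split(stemmed, factor(split_idx, levels = seq_along(toks)))
  out[as.integer(names(got))] <- got
  out
}

#' Build a synonym table from term groups
#'
#' Each group is a set of surface forms treated as equivalent for query
#' expansion (expansion is applied to queries only, never at indexing).
#' All terms are normalized by the same pipeline as documents, so lookups
#' happen in stem space.
#'
#' @param groups list of character vectors, one equivalence group each.
#' @return named list mapping each normalized term to the other
#'   normalized members of its group, with class `mr_synonyms`.
#' @seealso [read_synonyms()], [expand_terms()]
#' @export
synonym_table <- function(groups) {
  stopifnot(is.list(groups))
  norm_groups <- lapply(groups, function(g) {
    unique(unlist(lapply(g, normalize_terms), use.names = FALSE))
  })
  table <- list()
  for (g in norm_groups) {
    for (term in g) {
      table[[term]] <- unique(c(table[[term]], setdiff(g, term)))
    }
  }
  structure(table, class = "mr_synonyms")
}

#' Read a synonym table from a plain-text config file
#'
#' One synonym group per line, comma-separated; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return an `mr_synonyms` table (see [synonym_table()]).
#' @export
read_synonyms <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such synonym file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  groups <- lapply(strsplit(lines, ","), trimws)
  synonym_table(groups)
}

#' The synonym table shipped with the package
#'
#' A minimal COVID-related cluster (covid-19, sars-cov-2, coronavirus,
#' 2019-ncov and related coronavirus names), editable via
#' `inst/extdata/synonyms.txt`.
#'
#' @return an `mr_synonyms` table.
#' @export
default_synonym_table <- function() {
  read_synonyms(system.file("extdata", "synonyms.txt", package = "multiret",
                            mustWork = TRUE))
}

#' Expand a term sequence with synonyms
#'
#' Every input term is kept in order; each of its synonyms is appended
#' once immediately after the trigger term.  Duplicate input terms are
#' each expanded (multiset semantics), so the output is never shorter
#' than the input.
#'
#' @param terms character vector of normalized terms.
#' @param table an `mr_synonyms` table, or `NULL` for no expansion.
#' @return character vector of terms.
#' @export
expand_terms <- function(terms, table = NULL) {
  if (is.null(table) || length(terms) == 0L) return(terms)
  out <- lapply(terms, function(t) c(t, table[[t]]))
  unlist(out, use.names = FALSE)
}
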