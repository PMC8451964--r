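#' Read a document corpus from a metadata file
#'
#' Ingests CORD-19-style metadata: one record per publication with
#' `doc_id`, `title`, `abstract`, and optional `full_text`,
#' `publish_date` and `source` fields.  Two dialects are supported:
#' delimited text with a header (`"csv"`, `"tsv"`) and one JSON record
#' per line (`"jsonl"`).
#'
#' Dates are parsed leniently: `YYYY-MM-DD`, `YYYY-MM` (first of the
#' month) and `YYYY` (January 1) are accepted; anything else becomes
#' `NA`.  Titles and abstracts are never `NA` — absent values become
#' empty strings.
#'
#' @param path file path.
#' @param dialect one of `"csv"`, `"tsv"`, `"jsonl"`.
#' @return a tibble with columns `doc_id`, `title`, `abstract`,
#'   `full_text`, `publish_date` (`Date`), `source`, one row per record
#'   in file order.
#' @export
read_corpus <- function(path, dialect = c("csv", "tsv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_format(paste0("no such corpus file: ", path))
  if (dialect == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(
        doc_id = as.character(r$doc_id %||% NA_character_),
        title = as.character(r$title %||% ""),
        abstract = as.character(r$abstract %||% ""),
        full_text = as.character(r$full_text %||% NA_character_),
        publish_date = as.character(r$publish_date %||% NA_character_),
        source = as.character(r$source %||% ""),
        stringsAsFactors = FALSE
      )
    }))
    if (is.null(df)) df <- data.frame(doc_id = character())
  } else {
    sep <- if (dialect == "csv") "," else "\t"
    df <- read.csv(path, sep = sep, colClasses = "character",
                   stringsAsFactors = FALSE, check.names = TRUE)
  }
  required <- c("doc_id", "title", "abstract")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    abort_format(paste0("corpus file missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  for (col in c("full_text", "publish_date", "source")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  }
  if (anyNA(df$doc_id) || any(!nzchar(df$doc_id))) {
    abort_format("corpus contains empty doc_id")
  }
  dup <- unique(df$doc_id[duplicated(df$doc_id)])
  if (length(dup) > 0L) {
    abort_integrity(paste0("duplicate doc_id in corpus: ",
                           paste(head(dup, 5L), collapse = ", ")))
  }
  df$title[is.na(df$title)] <- ""
  df$abstract[is.na(df$abstract)] <- ""
  df$full_text[!is.na(df$full_text) & !nzchar(df$full_text)] <- NA_character_
  df$source[is.na(df$source)] <- ""
  tibble::tibble(
    doc_id = df$doc_id,
    title = df$title,
    abstract = df$abstract,
    full_text = df$full_text,
    publish_date = parse_lenient_date(df$publish_date),
    source = df$source
  )
}

#' Lenient publication-date parsing
#'
#' `YYYY-MM-DD` is taken as-is, `YYYY-MM` as the first of the month,
#' `YYYY` as January 1; anything unparseable becomes `NA`.
#'
#' @param x character vector of date strings.
#' @return a `Date` vector.
#' @export
parse_lenient_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  ym <- grepl("^\\d{4}-\\d{1,2}$", x)
  y <- grepl("^\\d{4}$", x)
  out[full] <- as.Date(x[full], format = "%Y-%m-%d")
  out[ym] <- as.Date(paste0(x[ym], "-01"), format = "%Y-%m-%d")
  out[y] <- as.Date(paste0(x[y], "-01-01"), format = "%Y-%m-%d")
  out
}

#' Write a corpus to a delimited metadata file
#'
#' @param corpus a corpus tibble as returned by [read_corpus()].
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(corpus)
  df$publish_date <- ifelse(is.na(df$publish_date), "",
                            format(df$publish_date, "%Y-%m-%d"))
  df$full_text[is.na(df$full_text)] <- ""
  write.table(df, path, sep = if (dialect == "csv") "," else "\t",
              row.names = FALSE, qmethod = "double", na = "")
  invisible(path)
}

#' Read a TREC-COVID-style topic file
#'
#' Topics are XML: a `<topics>` root with `<topic number="N">` children,
#' each carrying `<query>`, `<question>` and `<narrative>` elements.
#'
#' @param path file path.
#' @return a tibble with columns `number` (integer), `query`,
#'   `question`, `narrative` (whitespace-trimmed raw text).
#' @export
read_topics <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such topic file: ", path))
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//topic")
  if (length(nodes) == 0L) {
    return(tibble::tibble(number = integer(), query = character(),
                          question = character(), narrative = character()))
  }
  rows <- lapply(nodes, function(node) {
    number <- suppressWarnings(as.integer(xml2::xml_attr(node, "number")))
    if (is.na(number)) abort_format("topic element without a valid number attribute")
    fields <- vapply(c("query", "question", "narrative"), function(f) {
      el <- xml2::xml_find_first(node, paste0("./", f))
      if (inherits(el, "xml_missing")) {
        abort_format(paste0("topic ", number, " missing field element: ", f))
      }
      trimws(xml2::xml_text(el))
    }, character(1))
    tibble::tibble(number = number, query = fields[["query"]],
                   question = fields[["question"]],
                   narrative = fields[["narrative"]])
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$number)) abort_integrity("duplicate topic numbers")
  out
}

#' Write topics as TREC-COVID-style XML
#'
#' @param topics a topics tibble (see [read_topics()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topics <- function(topics, path) {
  root <- xml2::xml_new_root("topics")
  for (i in seq_len(nrow(topics))) {
    t <- xml2::xml_add_child(root, "topic", number = as.character(topics$number[i]))
    xml2::xml_add_child(t, "query", topics$query[i])
    xml2::xml_add_child(t, "question", topics$question[i])
    xml2::xml_add_child(t, "narrative", topics$narrative[i])
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read a TREC qrels file
#'
#' Whitespace-separated lines `topic iteration doc_id grade` with graded
#' judgments 0 (irrelevant), 1 (somewhat relevant), 2 (highly relevant).
#'
#' @param path file path.
#' @return a tibble with columns `topic` (integer), `doc_id`, `grade`
#'   (integer in 0..2).
#' @export
read_qrels <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such qrels file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(topic = integer(), doc_id = character(),
                          grade = integer()))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0L) {
    abort_format(paste0("malformed qrels line ", bad[1L]))
  }
  m <- do.call(rbind, parts)
  grade <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(grade) || any(!grade %in% 0:2)) {
    abort_format("qrels grade outside {0,1,2}")
  }
  topic <- suppressWarnings(as.integer(m[, 1L]))
  if (anyNA(topic)) abort_format("non-integer topic in qrels")
  qrels <- tibble::tibble(topic = topic, doc_id = m[, 3L], grade = grade)
  if (anyDuplicated(qrels[, c("topic", "doc_id")])) {
    abort_integrity("duplicate (topic, doc_id) pair in qrels")
  }
  qrels
}

#' Write a TREC qrels file
#'
#' @param qrels a qrels tibble (see [read_qrels()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qrels <- function(qrels, path) {
  writeLines(sprintf("%d 0 %s %d", qrels$topic, qrels$doc_id, qrels$grade),
             path)
  invisible(path)
}

#' Construct a run (ranked lists for a set of topics) from scores
#'
#' Sorts by descending score within topic, breaking ties by ascending
#' `doc_id`, and assigns consecutive ranks from 1.
#'
#' @param topic integer vector of topic numbers.
#' @param doc_id character vector of document ids.
#' @param score numeric scores.
#' @param tag run label.
#' @return a run tibble with columns `topic`, `doc_id`, `rank`, `score`,
#'   `tag`.
#' @export
as_run <- function(topic, doc_id, score, tag = "run") {
  stopifnot(length(topic) == length(doc_id), length(doc_id) == length(score))
  df <- tibble::tibble(topic = as.integer(topic), doc_id = as.character(doc_id),
                       score = as.numeric(score))
  df <- df[order(df$topic, -df$score, df$doc_id), ]
  df$rank <- unlist(lapply(split(seq_len(nrow(df)), df$topic), seq_along),
                    use.names = FALSE)
  df$tag <- tag
  validate_run(df[, c("topic", "doc_id", "rank", "score", "tag")])
}

# run invariants: per topic, ranks 1..n consecutive, unique doc ids,
# scores non-increasing with rank
validate_run <- function(run) {
  for (tp in split(run, run$topic)) {
    tp <- tp[order(tp$rank), ]
    if (!identical(as.integer(tp$rank), seq_len(nrow(tp)))) {
      abort_format(paste0("non-consecutive ranks for topic ", tp$topic[1L]))
    }
    if (anyDuplicated(tp$doc_id)) {
      abort_integrity(paste0("duplicate doc_id in topic ", tp$topic[1L]))
    }
    if (is.unsorted(rev(tp$score))) {
      abort_format(paste0("scores increase with rank for topic ", tp$topic[1L]))
    }
  }
  tibble::as_tibble(run)
}

#' Write a run in TREC format
#'
#' Lines are `topic Q0 doc_id rank score tag` with scores printed at six
#' decimal places; each topic is truncated to `depth` entries.
#'
#' @param run a run tibble (see [as_run()]).
#' @param path output file path.
#' @param depth maximum entries per topic (TREC convention: 1000).
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path, depth = 1000L) {
  stopifnot(depth >= 1L)
  run <- validate_run(run)
  run <- run[order(run$topic, run$rank), ]
  run <- dplyr::filter(run, .data$rank <= depth)
  writeLines(sprintf("%d Q0 %s %d %.6f %s",
                     run$topic, run$doc_id, run$rank, run$score, run$tag),
             path)
  invisible(path)
}

#' Read a TREC run file
#'
#' @param path file path.
#' @return a run tibble; ranks are validated to be consecutive from 1
#'   within each topic.
#' @export
read_run <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such run file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(topic = integer(), doc_id = character(),
                          rank = integer(), score = numeric(),
                          tag = character()))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 6L)
  if (length(bad) > 0L) abort_format(paste0("malformed run line ", bad[1L]))
  m <- do.call(rbind, parts)
  run <- tibble::tibble(
    topic = as.integer(m[, 1L]),
    doc_id = m[, 3L],
    rank = as.integer(m[, 4L]),
    score = as.numeric(m[, 5L]),
    tag = m[, 6L]
  )
  validate_run(run)
}
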