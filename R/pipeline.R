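#' Pipeline configuration
#'
#' Settings for [run_pipeline()], covering index construction, the
#' three weighting models, the fusion stages and the run recipes.  The
#' built-in recipes reproduce the seven submitted-run designs:
#'
#' * `M1` (*bm25*): BM25 against the metadata index.
#' * `M2` (*bow + rrf*): RRF of BM25, DFR and LMD computed against the
#'   metadata and full-text indices (six lists).
#' * `M3` (*mlm + rrf*): RRF of the registered second-stage rerankers
#'   applied to `M2`'s top `rerank_k` documents.
#' * `M4` (*bow + mlm + rrf*): RRF of `M2` and `M3`.
#' * `M5` (*bow + mlm + lm*): slot for a registered pairwise
#'   (LambdaMART-style) plug-in; a configuration error until one is
#'   registered.
#' * `M6` (*bow + mlm + lr*): logistic fusion over the similarity
#'   scores of the individual models behind `M2` and `M3`.
#' * `M7` (*bow + mlm + lr + rrf*): RRF of `M2`, `M3` and `M6`.
#'
#' @param recipes which recipes to produce.
#' @param models list of `mr_model` handles for the first stage.
#' @param rrf_k RRF threshold (60, the value tuned on earlier rounds;
#'   overridable).
#' @param rerank_k second-stage rerank depth (5000 in the study;
#'   effectively capped by the corpus size on fixtures).
#' @param top_k first-stage depth per query.
#' @param depth run-file truncation depth.
#' @param cutoff publication-date cutoff (documents strictly before it
#'   are dropped; default 2019-12-01, the outbreak-start filter).
#' @param keep_undated retain documents without a parseable date.
#' @param rerankers names of registered second-stage scorers.
#' @param pairwise_ranker registered pairwise plug-in name for `M5`, or
#'   `NULL`.
#' @param synonyms an `mr_synonyms` table, `NULL`, or `"default"` for
#'   the shipped table.
#' @param l2 L2 penalty of the logistic fusion stage.
#' @return a list with class `mr_config`.
#' @export
pipeline_config <- function(recipes = c("M1", "M2", "M3", "M4", "M6", "M7"),
                            models = list(weighting_model("bm25"),
                                          weighting_model("dfr"),
                                          weighting_model("lmd")),
                            rrf_k = 60,
                            rerank_k = 5000L,
                            top_k = 1000L,
                            depth = 1000L,
                            cutoff = as.Date("2019-12-01"),
                            keep_undated = TRUE,
                            rerankers = c("overlap_query", "overlap_question",
                                          "overlap_narrative"),
                            pairwise_ranker = NULL,
                            synonyms = "default",
                            l2 = 1e-3) {
  if (identical(synonyms, "default")) synonyms <- default_synonym_table()
  structure(list(recipes = recipes, models = models, rrf_k = rrf_k,
                 rerank_k = as.integer(rerank_k), top_k = as.integer(top_k),
                 depth = as.integer(depth), cutoff = cutoff,
                 keep_undated = keep_undated, rerankers = rerankers,
                 pairwise_ranker = pairwise_ranker, synonyms = synonyms,
                 l2 = l2),
            class = "mr_config")
}

# recipe dependency graph of the built-in pipeline
recipe_deps <- function() {
  list(M1 = character(), M2 = character(), M3 = "M2",
       M4 = c("M2", "M3"), M5 = c("M2", "M3"), M6 = c("M2", "M3"),
       M7 = c("M2", "M3", "M6"))
}

#' Resolve recipe execution order
#'
#' Topologically sorts the requested recipes together with their
#' dependencies; a cyclic dependency graph is a configuration error.
#'
#' @param requested character vector of recipe names.
#' @param deps named list mapping each recipe to its prerequisites
#'   (defaults to the built-in graph).
#' @return character vector of recipes in execution order.
#' @export
resolve_recipes <- function(requested, deps = recipe_deps()) {
  unknown <- setdiff(requested, names(deps))
  if (length(unknown) > 0L) {
    abort_config(paste0("unknown recipe(s): ", paste(unknown, collapse = ", ")))
  }
  order <- character()
  visiting <- character()
  visit <- function(name) {
    if (name %in% order) return(invisible())
    if (name %in% visiting) abort_config("cyclic recipe dependency graph")
    visiting <<- c(visiting, name)
    for (dep in deps[[name]]) visit(dep)
    visiting <<- setdiff(visiting, name)
    order <<- c(order, name)
  }
  for (name in requested) visit(name)
  order
}

#' Run the multistage retrieval pipeline
#'
#' Builds the metadata (and, when needed, full-text) indices, produces
#' the requested run recipes (see [pipeline_config()]), optionally
#' writes each as a TREC run file, and evaluates every produced run
#' when qrels are supplied.  The pipeline is fully deterministic:
#' identical inputs and config yield byte-identical run files.
#'
#' @param corpus a corpus tibble.
#' @param topics a topics tibble.
#' @param qrels a qrels tibble; required when a trained stage (`M5`,
#'   `M6`, `M7`) is requested, used for evaluation otherwise.
#' @param config an [pipeline_config()] object.
#' @param out_dir directory for TREC run files (created if needed), or
#'   `NULL` to skip writing.
#' @param verbose log per-stage timings and list sizes.
#' @return a list with `runs` (named list of run tibbles), `metrics`
#'   (named list of `mr_metrics`, when qrels given), `logistic_model`
#'   (when `M6` ran) and `files` (paths written).
#' @export
run_pipeline <- function(corpus, topics, qrels = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "mr_config"))
  order <- resolve_recipes(config$recipes)
  # fail on unresolvable plug-ins before any computation
  if (any(c("M3", "M4", "M5", "M6", "M7") %in% order)) {
    for (s in config$rerankers) get_scorer(s)
  }
  if ("M5" %in% order) {
    if (is.null(config$pairwise_ranker)) {
      abort_config("recipe M5 needs a registered pairwise ranker (pairwise_ranker)")
    }
    get_pairwise_ranker(config$pairwise_ranker)
  }
  if (any(c("M5", "M6", "M7") %in% order) && is.null(qrels)) {
    abort_config("trained recipes (M5/M6/M7) require training qrels")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(label, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(code)
    say("[%s] %.2fs%s", label, proc.time()[["elapsed"]] - t0,
        if (is.data.frame(res)) sprintf(" (%d entries)", nrow(res)) else "")
    res
  }

  indices <- list(metadata = stage("index metadata",
                                   build_index(corpus, "metadata")))
  need_fulltext <- any(c("M2", "M3", "M4", "M5", "M6", "M7") %in% order)
  if (need_fulltext) {
    indices$fulltext <- stage("index fulltext", build_index(corpus, "fulltext"))
  }

  search_args <- list(topics = topics, top_k = config$top_k,
                      cutoff = config$cutoff,
                      keep_undated = config$keep_undated,
                      synonyms = config$synonyms)
  first_stage <- list()
  for (model in config$models) {
    for (kind in names(indices)) {
      nm <- paste0(model$name, "-", substr(kind, 1L, 4L))
      first_stage[[nm]] <- stage(
        paste0("search ", nm),
        do.call(search_topics, c(list(index = indices[[kind]], model = model,
                                      tag = nm), search_args))
      )
    }
  }

  runs <- list()
  reranked <- list()
  logistic_model <- NULL
  for (name in order) {
    runs[[name]] <- switch(name,
      M1 = stage("M1 bm25", {
        r <- first_stage[["bm25-meta"]]
        r$tag <- "M1"
        r
      }),
      M2 = stage("M2 bow+rrf",
                 rrf_fuse_runs(first_stage, k = config$rrf_k, tag = "M2")),
      M3 = stage("M3 mlm+rrf", {
        k <- min(config$rerank_k, nrow(corpus))
        reranked <- lapply(setNames(config$rerankers, config$rerankers),
                            function(s) {
                              rerank_topk(runs$M2, s, corpus, topics,
                                          k = k, tag = s)
                            })
        rrf_fuse_runs(reranked, k = config$rrf_k, tag = "M3")
      }),
      M4 = stage("M4 bow+mlm+rrf",
                 rrf_fuse_runs(list(runs$M2, runs$M3), k = config$rrf_k,
                               tag = "M4")),
      M5 = stage("M5 bow+mlm+lm", {
        feats <- assemble_features(c(first_stage, reranked), qrels)
        ranker <- get_pairwise_ranker(config$pairwise_ranker)
        r <- ranker(feats, qrels)
        r$tag <- "M5"
        validate_run(r)
      }),
      M6 = stage("M6 bow+mlm+lr", {
        feats <- assemble_features(c(first_stage, reranked), qrels)
        logistic_model <- fit_logistic(feats, l2 = config$l2)
        score_logistic(logistic_model, feats, tag = "M6")
      }),
      M7 = stage("M7 bow+mlm+lr+rrf",
                 rrf_fuse_runs(list(runs$M2, runs$M3, runs$M6),
                               k = config$rrf_k, tag = "M7"))
    )
  }
  runs <- runs[intersect(config$recipes, names(runs))]

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (name in names(runs)) {
      path <- file.path(out_dir, paste0(name, ".run"))
      write_run(runs[[name]], path, depth = config$depth)
      files[name] <- path
    }
  }
  metrics <- NULL
  if (!is.null(qrels)) {
    metrics <- lapply(runs, evaluate_run, qrels = qrels)
  }
  list(runs = runs, metrics = metrics, logistic_model = logistic_model,
       files = files)
}
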