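#' Assemble a feature table from model runs
#'
#' Builds the learning-to-rank design: one row per (topic, document)
#' pair in the union of the input runs, one feature column per model
#' holding that model's similarity score.  A document not retrieved by
#' some model gets that model's per-topic minimum score minus a fixed
#' offset of 1 ("worse than anything it retrieved"), and the
#' corresponding `imputed_<model>` flag is set.  When qrels are given,
#' judged rows get a binary `label` (grades 1 and 2 are relevant, grade
#' 0 not); unjudged rows have `label = NA` and are excluded from
#' training by [fit_logistic()].
#'
#' @param runs a *named* list of run tibbles, one per contributing
#'   model.
#' @param qrels optional qrels tibble.
#' @param offset imputation offset below the per-topic minimum
#'   (default 1; features are standardized downstream, so only the
#'   ordering matters).
#' @return a tibble with columns `topic`, `doc_id`, one numeric column
#'   per model, one logical `imputed_<model>` column per model, and
#'   `label`; the model names are kept in the `features` attribute (a
#'   fixed feature order shared by [fit_logistic()] and
#'   [score_logistic()]).
#' @export
assemble_features <- function(runs, qrels = NULL, offset = 1) {
  if (length(runs) == 0L) abort_config("assemble_features needs at least one run")
  if (is.null(names(runs)) || any(!nzchar(names(runs)))) {
    abort_config("runs must be a named list (one name per model)")
  }
  pairs <- unique(dplyr::bind_rows(
    lapply(runs, function(r) r[, c("topic", "doc_id")])
  ))
  if (nrow(pairs) == 0L) abort_integrity("empty union of run documents")
  pairs <- pairs[order(pairs$topic, pairs$doc_id), ]
  out <- tibble::as_tibble(pairs)
  for (nm in names(runs)) {
    r <- runs[[nm]]
    idx <- match(paste(out$topic, out$doc_id), paste(r$topic, r$doc_id))
    score <- r$score[idx]
    imputed <- is.na(idx)
    # per-topic minimum of the model's observed scores, minus the offset;
    # topics the model skipped entirely fall back to the global minimum
    if (any(imputed)) {
      global_min <- if (all(is.na(score))) 0 else min(score, na.rm = TRUE)
      for (tn in unique(out$topic[imputed])) {
        sel <- out$topic == tn
        tmin <- if (all(is.na(score[sel]))) global_min else min(score[sel], na.rm = TRUE)
        score[sel & imputed] <- tmin - offset
      }
    }
    out[[nm]] <- score
    out[[paste0("imputed_", nm)]] <- imputed
  }
  if (!is.null(qrels)) {
    idx <- match(paste(out$topic, out$doc_id), paste(qrels$topic, qrels$doc_id))
    out$label <- ifelse(is.na(idx), NA_integer_,
                        as.integer(qrels$grade[idx] >= 1L))
  } else {
    out$label <- NA_integer_
  }
  attr(out, "features") <- names(runs)
  out
}

#' Fit the pointwise logistic score-fusion model
#'
#' Maximizes the L2-penalized binomial log-likelihood over the labeled
#' rows of a feature table by deterministic full-batch Newton ascent
#' from zero initialization (the intercept is not penalized).  Features
#' are standardized internally (per-feature z-score over the training
#' rows); the stored means/scales make scoring consistent.
#'
#' @param features a feature table from [assemble_features()] with at
#'   least one positive and one negative label.
#' @param l2 nonnegative L2 penalty on the weights (default 1e-3).
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the gradient max-norm.
#' @return an object of class `mr_logistic`: `weights` (standardized
#'   space), `bias`, `centers`, `scales`, `features`, `loss` (final
#'   penalized negative log-likelihood), `iterations`, `converged`.
#' @export
fit_logistic <- function(features, l2 = 1e-3, max_iter = 100L, tol = 1e-10) {
  stopifnot(l2 >= 0)
  feat_names <- attr(features, "features") %||%
    setdiff(names(features),
            c("topic", "doc_id", "label", grep("^imputed_", names(features), value = TRUE)))
  train <- features[!is.na(features$label), , drop = FALSE]
  y <- as.numeric(train$label)
  if (length(unique(y)) < 2L) {
    abort_training("training labels contain a single class")
  }
  x <- as.matrix(train[, feat_names, drop = FALSE])
  centers <- colMeans(x)
  scales <- apply(x, 2L, stats::sd)
  scales[scales == 0 | is.na(scales)] <- 1
  z <- sweep(sweep(x, 2L, centers), 2L, scales, "/")
  design <- cbind(`(bias)` = 1, z)
  p_pen <- c(0, rep(l2, ncol(z)))  # bias unpenalized
  beta <- numeric(ncol(design))
  converged <- FALSE
  iter <- 0L
  neg_ll <- function(beta) {
    eta <- drop(design %*% beta)
    log_denom <- ifelse(eta > 30, eta, log1p(exp(eta)))  # stable log(1+e^eta)
    -sum(y * eta - log_denom) + sum(p_pen * beta^2) / 2
  }
  for (iter in seq_len(max_iter)) {
    eta <- drop(design %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(design, y - p)) - p_pen * beta
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(p * (1 - p), 1e-10)
    hess <- crossprod(design * w, design) + diag(p_pen, ncol(design))
    step <- solve(hess, grad)
    # halve the step until the penalized likelihood does not worsen
    f0 <- neg_ll(beta)
    lambda <- 1
    while (neg_ll(beta + lambda * step) > f0 + 1e-12 && lambda > 1e-8) {
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
  }
  structure(list(
    weights = setNames(beta[-1L], feat_names),
    bias = beta[[1L]],
    centers = centers,
    scales = scales,
    features = feat_names,
    loss = neg_ll(beta),
    iterations = iter,
    converged = converged
  ), class = "mr_logistic")
}

#' @export
print.mr_logistic <- function(x, ...) {
  cat("<mr_logistic> ", length(x$weights), " features, ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations; loss ", format(x$loss), "\n", sep = "")
  invisible(x)
}

#' Score a feature table with a fitted logistic fusion model
#'
#' @param model an `mr_logistic`.
#' @param features a feature table from [assemble_features()] (same
#'   feature columns as at training time).
#' @param tag run label.
#' @return a run tibble ranking every (topic, document) row by model
#'   probability.
#' @export
score_logistic <- function(model, features, tag = "logistic") {
  stopifnot(inherits(model, "mr_logistic"))
  missing_cols <- setdiff(model$features, names(features))
  if (length(missing_cols) > 0L) {
    abort_config(paste0("feature table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(features[, model$features, drop = FALSE])
  z <- sweep(sweep(x, 2L, model$centers), 2L, model$scales, "/")
  eta <- drop(z %*% model$weights) + model$bias
  prob <- 1 / (1 + exp(-eta))
  as_run(features$topic, features$doc_id, prob, tag = tag)
}
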