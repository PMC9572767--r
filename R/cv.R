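#' Subject-grouped k-fold plan
#'
#' Shuffles the subjects by seed and deals them into k nearly equal test
#' sets (sizes differing by at most one); every fold trains on the
#' complement, so no subject ever appears in both sides of a fold. With 26
#' subjects and k = 5 this yields test sets of sizes 6, 5, 5, 5, 5 and 21
#' training subjects for each 5-subject test fold.
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return an object of class `mw_folds`: list of `k` elements, each with
#'   `train` and `test` subject-id vectors.
#' @export
make_group_folds <- function(subject_ids, k = 5L, seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds the %d subjects", k, n),
                  call. = FALSE)
  set.seed(seed)
  shuffled <- sample(subject_ids)
  assignment <- rep(seq_len(k), length.out = n)  # sizes differ by <= 1
  folds <- lapply(seq_len(k), function(f) {
    test <- shuffled[assignment == f]
    list(train = setdiff(subject_ids, test), test = test)
  })
  for (f in folds) {
    if (length(intersect(f$train, f$test)) > 0)
      stop("internal error: train/test subject overlap", call. = FALSE)
  }
  structure(folds, class = "mw_folds", k = k, seed = seed,
            subjects = subject_ids)
}

#' @export
print.mw_folds <- function(x, ...) {
  sizes <- vapply(x, function(f) length(f$test), integer(1))
  cat(sprintf("<mw_folds> k=%d over %d subjects; test sizes: %s\n",
              attr(x, "k"), length(attr(x, "subjects")),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Subject-grouped cross-validation of one preset
#'
#' For each fold, fits the preset on the training subjects' rows and
#' predicts the held-out subjects' rows; predictions are pooled across
#' folds and the pooled accuracy (correct / total) reported. Per-row
#' scores are retained for ROC construction. A fold whose training rows
#' contain a single class is skipped with a warning.
#'
#' @param spec an [model_spec()].
#' @param table an `mw_feature_table`.
#' @param plan an [make_group_folds()] plan covering the table's subjects.
#' @param features optional restriction to a feature subset.
#' @return list with `accuracy` (pooled), `fold_accuracy`, and
#'   `predictions` (data.frame: `subject_id`, `phase`, `truth`, `pred`,
#'   `fold`, plus one `score_<class>` column per class).
#' @export
cross_validate <- function(spec, table, plan, features = NULL) {
  stopifnot(inherits(plan, "mw_folds"))
  extra <- setdiff(unique(table$subject_id), attr(plan, "subjects"))
  if (length(extra) > 0)
    stop("table contains subjects absent from the fold plan: ",
         paste(extra, collapse = ", "), call. = FALSE)
  classes <- sort(unique(table$label))
  preds <- list()
  fold_acc <- rep(NA_real_, length(plan))
  for (f in seq_along(plan)) {
    tr_rows <- table[table$subject_id %in% plan[[f]]$train, , drop = FALSE]
    te_rows <- table[table$subject_id %in% plan[[f]]$test, , drop = FALSE]
    if (nrow(te_rows) == 0L) next
    if (length(unique(tr_rows$label)) < 2L) {
      warning(sprintf("fold %d skipped: single training class", f),
              call. = FALSE)
      next
    }
    model <- fit(make_model(spec), tr_rows, features = features)
    out <- predict_scores(model, te_rows)
    sc <- matrix(NA_real_, nrow(te_rows), length(classes),
                 dimnames = list(NULL, paste0("score_", classes)))
    sc[, paste0("score_", colnames(out$scores))] <- out$scores
    phase <- if (is.null(te_rows$phase)) NA_character_ else te_rows$phase
    preds[[f]] <- data.frame(
      subject_id = te_rows$subject_id, phase = phase,
      truth = te_rows$label, pred = out$labels, fold = f, sc,
      check.names = FALSE)
    fold_acc[f] <- mean(out$labels == te_rows$label)
  }
  if (length(preds) == 0L)
    stop("no fold produced predictions", call. = FALSE)
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  list(accuracy = mean(predictions$pred == predictions$truth),
       fold_accuracy = fold_acc,
       predictions = predictions)
}

#' Repeated subject-grouped cross-validation
#'
#' Repeats [cross_validate()] over independently shuffled fold plans and
#' reports the mean pooled accuracy with the per-repetition values, the
#' standard way to smooth the fold-assignment lottery in small cohorts.
#'
#' @param spec an [model_spec()].
#' @param table an `mw_feature_table`.
#' @param repetitions number of shuffled plans.
#' @param k folds per plan.
#' @param seed base seed; repetition `i` uses `seed + i - 1`.
#' @param features optional feature subset.
#' @return list with `mean_accuracy` and `accuracy` (per repetition).
#' @export
repeat_cv <- function(spec, table, repetitions = 20L, k = 5L, seed = 1L,
                      features = NULL) {
  subjects <- unique(table$subject_id)
  acc <- vapply(seq_len(repetitions), function(i) {
    plan <- make_group_folds(subjects, k = k, seed = seed + i - 1L)
    cross_validate(spec, table, plan, features = features)$accuracy
  }, numeric(1))
  list(mean_accuracy = mean(acc), accuracy = acc)
}

# Draw `n_subsets` distinct non-empty feature subsets: subset size uniform
# on 1..d, then a uniform subset of that size; duplicates rejected.
draw_subsets <- function(features, n_subsets, seed) {
  d <- length(features)
  n_possible <- if (d < 31) 2^d - 1 else Inf
  if (n_possible < n_subsets) {
    warning(sprintf(
      "only %d distinct subsets exist; enumerating all instead of %d",
      n_possible, n_subsets), call. = FALSE)
    subsets <- list()
    for (size in seq_len(d))
      subsets <- c(subsets, utils::combn(features, size, simplify = FALSE))
    return(subsets)
  }
  set.seed(seed)
  subsets <- list()
  seen <- character(0)
  while (length(subsets) < n_subsets) {
    size <- sample.int(d, 1)
    s <- sort(sample(features, size))
    key <- paste(s, collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    subsets[[length(subsets) + 1L]] <- s
  }
  subsets
}

#' Wrapper feature selection over random subsets
#'
#' Draws `n_subsets` distinct random feature subsets, scores each by
#' subject-grouped cross-validated accuracy of the given preset restricted
#' to those columns, and returns the best. Ties are broken toward the
#' smaller subset, then lexicographically.
#'
#' @param spec an [model_spec()].
#' @param table an `mw_feature_table`.
#' @param plan an [make_group_folds()] plan.
#' @param n_subsets number of random subsets to evaluate (default 50).
#' @param seed subset-sampling seed.
#' @return an object of class `mw_selection`: list with `chosen`
#'   (character vector), `chosen_accuracy`, and `evaluated` (data.frame of
#'   subset / size / accuracy for every draw).
#' @export
wrapper_select <- function(spec, table, plan, n_subsets = 50L, seed = 1L) {
  features <- feature_columns(table)
  if (length(features) < 1L)
    stop("table has no feature columns", call. = FALSE)
  subsets <- draw_subsets(features, n_subsets, seed)
  acc <- vapply(subsets, function(s)
    cross_validate(spec, table, plan, features = s)$accuracy, numeric(1))
  keys <- vapply(subsets, paste, "", collapse = "|")
  sizes <- lengths(subsets)
  ord <- order(-acc, sizes, keys)
  best <- ord[1]
  structure(
    list(chosen = subsets[[best]],
         chosen_accuracy = acc[best],
         evaluated = data.frame(subset = keys, size = sizes,
                                accuracy = acc)),
    class = "mw_selection", seed = seed)
}

#' @export
print.mw_selection <- function(x, ...) {
  cat(sprintf(
    "<mw_selection> %d subsets evaluated; best accuracy %.3f with {%s}\n",
    nrow(x$evaluated), x$chosen_accuracy, paste(x$chosen, collapse = ", ")))
  invisible(x)
}

#' Serialize a fold plan or selection result to JSON
#'
#' @param x an `mw_folds` or `mw_selection` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(x, path) {
  obj <- if (inherits(x, "mw_folds")) {
    list(k = attr(x, "k"), seed = attr(x, "seed"),
         subjects = attr(x, "subjects"),
         folds = lapply(x, function(f) list(train = f$train,
                                            test = f$test)))
  } else if (inherits(x, "mw_selection")) {
    list(seed = attr(x, "seed"), chosen = x$chosen,
         chosen_accuracy = x$chosen_accuracy, evaluated = x$evaluated)
  } else stop("unsupported object", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
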