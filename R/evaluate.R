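#' Confusion matrix and derived classification metrics
#'
#' Builds the class-by-class count matrix (rows = truth, columns =
#' prediction) and the per-class one-vs-rest sensitivity, specificity,
#' precision and F1 = 2PR/(P+R), plus their unweighted macro averages and
#' the overall accuracy (trace / total). A class absent from the truth gets
#' `NA` sensitivity.
#'
#' @param truth,pred equal-length label vectors.
#' @param classes class set (defaults to the union of observed labels).
#' @return an object of class `mw_eval`: list with `confusion`,
#'   `accuracy`, `per_class` (data.frame) and `macro` (named vector).
#' @export
confusion_and_metrics <- function(truth, pred, classes = NULL) {
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  if (length(truth) != length(pred))
    stop("truth and predictions differ in length", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  if (anyNA(truth) || anyNA(pred))
    stop("labels outside the class set", call. = FALSE)
  cm <- table(truth = truth, pred = pred)
  n <- sum(cm)
  per <- do.call(rbind, lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    data.frame(class = classes[i], sensitivity = sens, specificity = spec,
               precision = prec, f1 = f1)
  }))
  structure(
    list(confusion = unclass(cm),
         accuracy = sum(diag(cm)) / n,
         per_class = per,
         macro = c(sensitivity = mean(per$sensitivity),
                   specificity = mean(per$specificity),
                   precision = mean(per$precision),
                   f1 = mean(per$f1))),
    class = "mw_eval")
}

#' @export
print.mw_eval <- function(x, ...) {
  cat(sprintf("<mw_eval> accuracy %.3f\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' ROC curve and AUC for one positive class
#'
#' Sweeps the sorted distinct scores (plus infinite endpoints) as
#' thresholds to build a step-exact ROC, and computes the AUC as the
#' Mann-Whitney statistic: the proportion of (positive, negative) pairs
#' ranked correctly, with half credit for ties.
#'
#' @param truth label vector containing both the positive class and at
#'   least one other label.
#' @param scores numeric score per row (higher = more positive).
#' @param positive the positive class label.
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(truth, scores, positive) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both the positive class and its complement must be represented",
         call. = FALSE)
  r <- rank(scores)  # mean ranks give tie half-credit
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores[!pos] >= t) / n0, numeric(1)),
    tpr = vapply(thr, function(t) sum(scores[pos] >= t) / n1, numeric(1)))
  list(roc = roc, auc = auc)
}

#' One-vs-rest ROC curves for a multiclass problem
#'
#' One binary ROC per class against the union of the remaining classes
#' (e.g. immediate recall vs the cumulative delayed-recall + recognition
#' class), plus the unweighted macro-average AUC.
#'
#' @param truth label vector.
#' @param score_matrix numeric matrix, one column per class (column names
#'   are the class labels).
#' @return list with `per_class` (named list of [roc_auc()] results) and
#'   `macro_auc`.
#' @export
one_vs_rest_rocs <- function(truth, score_matrix) {
  score_matrix <- as.matrix(score_matrix)
  classes <- colnames(score_matrix)
  if (is.null(classes))
    stop("score matrix must have class labels as column names",
         call. = FALSE)
  per <- lapply(classes, function(cl)
    roc_auc(truth, score_matrix[, cl], positive = cl))
  names(per) <- classes
  list(per_class = per,
       macro_auc = mean(vapply(per, `[[`, numeric(1), "auc")))
}

#' Paired t-test
#'
#' Two-sided paired t-test on subject-matched measurements: t =
#' mean(d) / (sd(d)/sqrt(n)) with d = a - b and n - 1 degrees of freedom.
#' When the differences have zero variance the statistic is undefined and
#' flagged rather than raising an error.
#'
#' @param a,b equal-length paired numeric vectors (n >= 2).
#' @return an object of class `mw_ttest`: list with `t`, `dof`, `p`, `n`
#'   and `undefined`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("at least 2 pairs required", call. = FALSE)
  if (stats::sd(a - b) == 0) {
    return(structure(list(t = NA_real_, dof = n - 1L, p = NA_real_, n = n,
                          undefined = TRUE), class = "mw_ttest"))
  }
  res <- tryCatch(stats::t.test(a, b, paired = TRUE),
                  error = function(e) NULL)
  if (is.null(res)) {
    return(structure(list(t = NA_real_, dof = n - 1L, p = NA_real_, n = n,
                          undefined = TRUE), class = "mw_ttest"))
  }
  structure(list(t = unname(res$statistic), dof = unname(res$parameter),
                 p = res$p.value, n = n, undefined = FALSE),
            class = "mw_ttest")
}

#' @export
print.mw_ttest <- function(x, ...) {
  if (x$undefined) cat("<mw_ttest> undefined (zero-variance differences)\n")
  else cat(sprintf("<mw_ttest> t = %.3f, dof = %d, p = %.4g\n",
                   x$t, x$dof, x$p))
  invisible(x)
}

#' Per-feature paired comparisons across phases
#'
#' For every feature column and every pair of task phases, runs a paired
#' t-test across subjects and marks significance at p < 0.05 (`*`) and
#' p < 0.01 (`**`), unadjusted; a Holm-adjusted p-value column is included
#' separately for users who want family-wise control.
#'
#' @param table an `mw_feature_table` in which every subject has a row for
#'   every phase.
#' @return data.frame with columns `feature`, `phase_a`, `phase_b`, `t`,
#'   `dof`, `p`, `stars`, `p_holm`.
#' @export
feature_phase_comparison <- function(table) {
  phases <- unique(table$phase)
  feats <- feature_columns(table)
  subjects <- sort(unique(table$subject_id))
  for (ph in phases) {
    have <- table$subject_id[table$phase == ph]
    missing <- setdiff(subjects, have)
    if (length(missing) > 0)
      stop(sprintf("unbalanced pairing: subject(s) %s lack phase %s",
                   paste(missing, collapse = ", "), ph), call. = FALSE)
  }
  pairs <- utils::combn(phases, 2, simplify = FALSE)
  rows <- list()
  for (f in feats) {
    for (pp in pairs) {
      a <- table[[f]][match(paste(subjects, pp[1]),
                            paste(table$subject_id, table$phase))]
      b <- table[[f]][match(paste(subjects, pp[2]),
                            paste(table$subject_id, table$phase))]
      ok <- stats::complete.cases(a, b)
      tt <- paired_t_test(a[ok], b[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, phase_a = pp[1], phase_b = pp[2],
        t = tt$t, dof = tt$dof, p = tt$p)
    }
  }
  out <- do.call(rbind, rows)
  out$stars <- ifelse(is.na(out$p), "",
                      ifelse(out$p < 0.01, "**",
                             ifelse(out$p < 0.05, "*", "")))
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Full evaluation report for pooled CV predictions
#'
#' Combines the confusion matrix and derived metrics with ROC/AUC: a
#' single curve for two-class tasks (class 1 as positive) and one-vs-rest
#' curves with a macro AUC for multiclass tasks.
#'
#' @param predictions data.frame from [cross_validate()] (`truth`, `pred`
#'   and `score_<class>` columns).
#' @return an object of class `mw_report`: the [confusion_and_metrics()]
#'   list extended with `auc` and `roc` entries.
#' @export
evaluation_report <- function(predictions) {
  classes <- sort(unique(predictions$truth))
  ev <- confusion_and_metrics(predictions$truth, predictions$pred,
                              classes = classes)
  score_cols <- paste0("score_", classes)
  sc <- as.matrix(predictions[, score_cols, drop = FALSE])
  colnames(sc) <- as.character(classes)
  if (length(classes) == 2L) {
    r <- roc_auc(predictions$truth, sc[, 2], positive = classes[2])
    ev$auc <- r$auc
    ev$roc <- list(r$roc)
    names(ev$roc) <- as.character(classes[2])
  } else {
    r <- one_vs_rest_rocs(predictions$truth, sc)
    ev$auc <- r$macro_auc
    ev$per_class$auc <- vapply(r$per_class, `[[`, numeric(1), "auc")
    ev$roc <- lapply(r$per_class, `[[`, "roc")
  }
  class(ev) <- c("mw_report", class(ev))
  ev
}

#' @export
print.mw_report <- function(x, ...) {
  cat(sprintf("<mw_report> accuracy %.3f, AUC %.3f\n", x$accuracy, x$auc))
  print(x$confusion)
  invisible(x)
}
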