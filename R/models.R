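MODEL_PRESETS <- list(
  decision_tree = c("simple", "medium", "complex"),
  discriminant = c("linear", "quadratic"),
  logistic_regression = "default",
  svm = c("linear", "quadratic", "cubic"),
  knn = c("coarse", "medium", "fine"),
  ensemble = c("bagged_trees", "subspace_discriminant", "subspace_knn",
               "rusboost_trees")
)

# Families whose inputs are z-scored inside the fit (trees are scale-free).
SCALED_FAMILIES <- c("discriminant", "logistic_regression", "svm", "knn")

#' All sixteen classifier presets
#'
#' @return a data.frame with columns `family` and `preset`, one row per
#'   preset (3 decision trees, 2 discriminants, logistic regression, 3
#'   SVMs, 3 kNNs, 4 ensembles).
#' @export
model_presets <- function() {
  do.call(rbind, lapply(names(MODEL_PRESETS), function(f)
    data.frame(family = f, preset = MODEL_PRESETS[[f]])))
}

#' Specify a classifier
#'
#' Names one of the sixteen presets across the six model families:
#' decision trees (simple/medium/complex, i.e. at most 4/20/100 splits),
#' discriminant analysis (linear/quadratic), logistic regression (binary
#' tasks only), polynomial-kernel SVMs (linear/quadratic/cubic), k-nearest
#' neighbours (coarse/medium/fine, k = 100/10/1) and ensembles (bagged
#' trees, subspace discriminant, subspace kNN, RUS-boosted trees; 30
#' learners each).
#'
#' @param family one of `decision_tree`, `discriminant`,
#'   `logistic_regression`, `svm`, `knn`, `ensemble`.
#' @param preset variant name within the family (see above).
#' @param seed integer seed controlling any randomness in the fit
#'   (bootstraps, subspaces, under-sampling).
#' @param task optional task name; specifying `logistic_regression` for the
#'   three-class `"RAVLT"` task errors immediately (the model is
#'   binary-only).
#' @return an object of class `mw_model_spec`.
#' @export
model_spec <- function(family, preset = NULL, seed = 1L, task = NULL) {
  if (!family %in% names(MODEL_PRESETS))
    stop(sprintf("unknown family '%s'; valid families: %s", family,
                 paste(names(MODEL_PRESETS), collapse = ", ")),
         call. = FALSE)
  valid <- MODEL_PRESETS[[family]]
  if (is.null(preset)) preset <- valid[1]
  if (!preset %in% valid)
    stop(sprintf("unknown preset '%s' for %s; valid presets: %s",
                 preset, family, paste(valid, collapse = ", ")),
         call. = FALSE)
  if (family == "logistic_regression" && !is.null(task) && task == "RAVLT")
    stop("logistic_regression is not applicable (binary-only)",
         call. = FALSE)
  structure(list(family = family, preset = preset, seed = as.integer(seed)),
            class = "mw_model_spec")
}

#' @export
print.mw_model_spec <- function(x, ...) {
  cat(sprintf("<mw_model_spec> %s / %s (seed %d)\n",
              x$family, x$preset, x$seed))
  invisible(x)
}

#' Instantiate an untrained learner from a spec
#'
#' @param spec an [model_spec()] object.
#' @return an object of class `mw_learner`, to be passed to [fit()].
#' @export
make_model <- function(spec) {
  stopifnot(inherits(spec, "mw_model_spec"))
  structure(list(spec = spec), class = "mw_learner")
}

#' Fit a classifier to a feature table
#' @param object an `mw_learner` (or `mw_model_spec`).
#' @param ... passed to methods.
#' @export
fit <- function(object, ...) UseMethod("fit")

#' @export
fit.mw_model_spec <- function(object, table, ...) fit(make_model(object), table, ...)

# ---- quadratic discriminant with covariance shrinkage -------------------
# Per-class Gaussian scores with the class covariance shrunk toward a
# scaled identity so the model remains usable when the feature count
# approaches the per-class sample count.
rqda_train <- function(x, y, gamma = 0.1) {
  classes <- levels(y)
  p <- ncol(x)
  models <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xi)
    S <- if (nrow(xi) > 1) stats::cov(xi) else diag(1, p)
    tr <- sum(diag(S))
    target <- diag(max(tr / p, 1e-8), p)
    Sr <- (1 - gamma) * S + gamma * target
    # ridge escalation if still numerically singular
    ridge <- 0
    repeat {
      ch <- tryCatch(chol(Sr + diag(ridge, p)), error = function(e) NULL)
      if (!is.null(ch)) break
      ridge <- if (ridge == 0) 1e-6 * max(tr / p, 1) else ridge * 10
    }
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))),
         logprior = log(mean(y == cl)))
  })
  names(models) <- classes
  models
}

rqda_scores <- function(models, x) {
  sc <- vapply(models, function(m) {
    d <- sweep(x, 2, m$mu)
    z <- backsolve(m$chol, t(d), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * m$logdet + m$logprior
  }, numeric(nrow(x)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
  sc
}

# ---- decision trees pruned to a split budget ----------------------------
fit_tree <- function(x, y, max_splits) {
  df <- data.frame(.y = y, x, check.names = FALSE)
  tr <- rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(
                       cp = 0, minsplit = 2, minbucket = 1, xval = 0,
                       maxsurrogate = 0, maxcompete = 0))
  cp <- tr$cptable
  ok <- cp[cp[, "nsplit"] <= max_splits, , drop = FALSE]
  rpart::prune(tr, cp = ok[nrow(ok), "CP"])
}

tree_scores <- function(tr, x) {
  stats::predict(tr, data.frame(x, check.names = FALSE), type = "prob")
}

# ---- RUS-boosted trees (SAMME with per-round under-sampling) ------------
fit_rusboost <- function(x, y, n_learners = 30, maxdepth = 4) {
  n <- nrow(x); K <- nlevels(y)
  w <- rep(1 / n, n)
  n_min <- min(table(y))
  learners <- list(); alphas <- numeric(0)
  df_all <- data.frame(.y = y, x, check.names = FALSE)
  for (t in seq_len(n_learners)) {
    idx <- unlist(lapply(levels(y), function(cl) {
      pool <- which(y == cl)
      if (length(pool) <= n_min) pool
      else sample(pool, n_min, prob = w[pool] / sum(w[pool]))
    }))
    tr <- rpart::rpart(.y ~ ., data = df_all[idx, , drop = FALSE],
                       method = "class",
                       control = rpart::rpart.control(
                         cp = 0, minsplit = 2, minbucket = 1, xval = 0,
                         maxdepth = maxdepth, maxsurrogate = 0,
                         maxcompete = 0))
    pred <- stats::predict(tr, df_all, type = "class")
    miss <- pred != y
    eps <- sum(w[miss])
    if (eps >= 1 - 1 / K) { w <- rep(1 / n, n); next }
    alpha <- if (eps <= 0) 10 else log((1 - eps) / eps) + log(K - 1)
    learners[[length(learners) + 1L]] <- tr
    alphas <- c(alphas, alpha)
    if (eps <= 0) break
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  list(learners = learners, alphas = alphas, classes = levels(y))
}

rusboost_scores <- function(model, x) {
  df <- data.frame(x, check.names = FALSE)
  sc <- matrix(0, nrow(x), length(model$classes),
               dimnames = list(NULL, model$classes))
  for (t in seq_along(model$learners)) {
    pred <- as.character(stats::predict(model$learners[[t]], df,
                                        type = "class"))
    sc[cbind(seq_len(nrow(x)), match(pred, model$classes))] <-
      sc[cbind(seq_len(nrow(x)), match(pred, model$classes))] +
      model$alphas[t]
  }
  sc
}

# ---- random-subspace ensembles ------------------------------------------
fit_subspace <- function(x, y, base, n_learners = 30) {
  p <- ncol(x)
  d <- max(1L, p %/% 2L)
  members <- list()
  for (t in seq_len(n_learners)) {
    fcols <- sort(sample.int(p, d))
    m <- tryCatch(base$train(x[, fcols, drop = FALSE], y),
                  error = function(e) NULL)
    if (!is.null(m)) members[[length(members) + 1L]] <-
        list(cols = fcols, model = m)
  }
  if (length(members) == 0L)
    stop("no subspace learner could be trained", call. = FALSE)
  list(members = members, base = base, classes = levels(y))
}

subspace_scores <- function(model, x) {
  acc <- matrix(0, nrow(x), length(model$classes),
                dimnames = list(NULL, model$classes))
  for (mem in model$members) {
    sc <- model$base$score(mem$model, x[, mem$cols, drop = FALSE])
    acc <- acc + sc[, model$classes, drop = FALSE]
  }
  acc / length(model$members)
}

subspace_lda_base <- list(
  train = function(x, y)
    suppressWarnings(MASS::lda(x, grouping = y)),
  score = function(m, x)
    stats::predict(m, x)$posterior
)

subspace_knn_base <- list(
  train = function(x, y) caret::knn3(x, y, k = 1),
  score = function(m, x) stats::predict(m, x, type = "prob")
)

# ---- unified fit --------------------------------------------------------

#' @describeIn fit Train a preset on an `mw_feature_table` (or any
#'   data.frame with a `label` column and feature columns). Scale-sensitive
#'   families (SVM, kNN, discriminant, logistic) are z-scored internally on
#'   the training rows only.
#' @param table feature table with a `label` column.
#' @param features optional character vector restricting the feature
#'   columns used.
#' @return `fit()` returns an `mw_model` supporting [predict_scores()].
#' @export
fit.mw_learner <- function(object, table, features = NULL, ...) {
  spec <- object$spec
  if (is.null(features)) {
    features <- if (inherits(table, "mw_feature_table"))
      feature_columns(table)
    else setdiff(names(table), c("subject_id", "task", "phase", "label"))
  }
  miss <- setdiff(features, names(table))
  if (length(miss) > 0)
    stop("missing feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(table[, features, drop = FALSE])
  storage.mode(x) <- "double"
  y <- factor(table$label, levels = sort(unique(table$label)))
  if (nlevels(y) < 2L)
    stop("training data contain a single class", call. = FALSE)
  if (any(table(y) < 2L))
    stop("each class needs at least 2 training rows", call. = FALSE)
  if (spec$family == "logistic_regression" && nlevels(y) > 2L)
    stop("logistic_regression is not applicable (binary-only)",
         call. = FALSE)

  center <- NULL; scale_ <- NULL
  scaled <- spec$family %in% SCALED_FAMILIES ||
    (spec$family == "ensemble" &&
       spec$preset %in% c("subspace_discriminant", "subspace_knn"))
  if (scaled) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  }

  set.seed(spec$seed)
  fitted <- switch(
    spec$family,
    decision_tree = fit_tree(x, y, switch(spec$preset, simple = 4,
                                          medium = 20, complex = 100)),
    discriminant = if (spec$preset == "linear")
      suppressWarnings(MASS::lda(x, grouping = y))
    else rqda_train(x, y),
    logistic_regression = suppressWarnings(
      stats::glm.fit(cbind(1, x), as.integer(y) - 1L,
                     family = stats::binomial())),
    svm = {
      kern <- if (spec$preset == "linear") "linear" else "polynomial"
      deg <- switch(spec$preset, linear = 1, quadratic = 2, cubic = 3)
      e1071::svm(x, y, kernel = kern, degree = deg, coef0 = 1, cost = 1,
                 scale = FALSE)
    },
    knn = {
      k <- switch(spec$preset, coarse = 100, medium = 10, fine = 1)
      caret::knn3(x, y, k = min(k, nrow(x)))
    },
    ensemble = switch(
      spec$preset,
      bagged_trees = randomForest::randomForest(x, y, ntree = 30,
                                                mtry = ncol(x)),
      subspace_discriminant = fit_subspace(x, y, subspace_lda_base),
      subspace_knn = fit_subspace(x, y, subspace_knn_base),
      rusboost_trees = fit_rusboost(x, y))
  )

  structure(
    list(spec = spec, fitted = fitted, classes = levels(y),
         features = features, center = center, scale = scale_),
    class = "mw_model")
}

#' @export
print.mw_model <- function(x, ...) {
  cat(sprintf("<mw_model> %s / %s: %d features, classes {%s}\n",
              x$spec$family, x$spec$preset, length(x$features),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

# Raw per-class score matrix on standardized x.
model_scores <- function(model, x) {
  spec <- model$spec
  K <- length(model$classes)
  sc <- switch(
    spec$family,
    decision_tree = tree_scores(model$fitted, x),
    discriminant = if (spec$preset == "linear")
      stats::predict(model$fitted, x)$posterior
    else rqda_scores(model$fitted, x),
    logistic_regression = {
      coefs <- model$fitted$coefficients
      coefs[is.na(coefs)] <- 0  # rank-deficient columns contribute nothing
      eta <- drop(cbind(1, x) %*% coefs)
      p1 <- stats::plogis(eta)
      cbind(`0` = 1 - p1, `1` = p1)
    },
    svm = {
      pr <- stats::predict(model$fitted, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      sc <- matrix(0, nrow(x), K, dimnames = list(NULL, model$classes))
      for (cn in colnames(dv)) {
        ab <- strsplit(cn, "/", fixed = TRUE)[[1]]
        sc[, ab[1]] <- sc[, ab[1]] + dv[, cn]
        sc[, ab[2]] <- sc[, ab[2]] - dv[, cn]
      }
      sc
    },
    knn = stats::predict(model$fitted, x, type = "prob"),
    ensemble = switch(
      spec$preset,
      bagged_trees = stats::predict(model$fitted, x, type = "prob"),
      subspace_discriminant = subspace_scores(model$fitted, x),
      subspace_knn = subspace_scores(model$fitted, x),
      rusboost_trees = rusboost_scores(model$fitted, x))
  )
  sc <- as.matrix(sc)
  colnames(sc) <- model$classes
  sc
}

#' Per-class scores and predicted labels
#'
#' Applies a trained model to new rows, returning one score per class per
#' row (higher = more likely) and the predicted label, defined as the
#' argmax with ties broken toward the lowest class index.
#'
#' @param model an `mw_model` from [fit()].
#' @param rows a data.frame carrying the training feature columns.
#' @return list with `scores` (numeric matrix, one column per class) and
#'   `labels` (integer vector of predicted class labels).
#' @export
predict_scores <- function(model, rows) {
  stopifnot(inherits(model, "mw_model"))
  miss <- setdiff(model$features, names(rows))
  if (length(miss) > 0)
    stop("missing feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(rows[, model$features, drop = FALSE])
  storage.mode(x) <- "double"
  if (!is.null(model$center))
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  sc <- model_scores(model, x)
  labels <- as.integer(model$classes[apply(sc, 1, which.max)])
  list(scores = sc, labels = labels)
}

#' @export
predict.mw_model <- function(object, newdata, ...) {
  predict_scores(object, newdata)$labels
}
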