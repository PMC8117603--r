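#' Default hyperparameter grids
#'
#' Small grids searched during training: exhaustive for the RBF SVM (cost and
#' kernel width, its only two tuned parameters), staged coordinate-wise for
#' the tree ensembles (random forest: trees, then depth, then minimum node
#' size; gradient boosting: depth, then learning rate, then rounds). In each
#' list the values are ordered simplest first; ties in cross-validated AUC
#' keep the earlier value.
#'
#' @param algo `"svm_rbf"`, `"random_forest"` or `"gbt"`.
#' @return Named list of candidate value vectors, in staged search order.
#' @export
default_grid <- function(algo = c("svm_rbf", "random_forest", "gbt")) {
  switch(match.arg(algo),
    svm_rbf = list(cost = c(0.1, 1, 10, 100),
                   gamma = c(1e-3, 1e-2, 1e-1, 1)),
    random_forest = list(num.trees = c(200, 500),
                         max.depth = c(0, 10, 20),   # 0 = unlimited
                         min.node.size = c(2, 5)),
    gbt = list(max_depth = c(3, 6),
               eta = c(0.05, 0.1, 0.3),
               nrounds = c(100, 300)))
}

## deterministic stratified fold assignment; relies on the caller's RNG state
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train and evaluate a transcript classifier
#'
#' Fits one of three classifier families to a labeled [build_feature_table()]
#' under stratified 5-fold cross-validation. Within each training fold, a
#' grid search (exhaustive for the SVM, staged for the tree models; see
#' [default_grid()]) scored by inner 5-fold mean AUC selects the
#' hyperparameters; the held-out fold is then scored, and the pooled
#' out-of-fold scores yield the ROC/AUC and PR/AUPR. A final model is refit
#' on all rows with the modal (ties: first) fold-winning hyperparameters.
#' `lncRNA` is the positive class. All randomness derives from `seed`; the
#' same table and seed reproduce identical scores.
#'
#' SVM features are z-scored inside each fold (RBF kernels are
#' scale-sensitive; trees are not) and its scores are a monotone logistic
#' link of the decision values, so ranking metrics are unaffected.
#'
#' @param x A labeled `feature_table` with both classes, at least `folds`
#'   rows per class.
#' @param algo `"svm_rbf"`, `"random_forest"` or `"gbt"`.
#' @param seed Integer master seed.
#' @param folds Outer cross-validation folds (default 5).
#' @param grid Hyperparameter grid; default [default_grid()] for `algo`.
#' @param inner_folds Inner folds used to score grid candidates (default 5).
#' @return An object of class `lnc_model` with components `algo`,
#'   `hyperparams`, `fold_hyperparams`, `scores` (pooled out-of-fold, named
#'   by transcript id), `labels`, `fold_id`, `roc`, `auc`, `pr`, `aupr`,
#'   `importance` (tree models), `seed`, `feature_set`.
#' @examples
#' \donttest{
#' ts <- generate_dataset(synthetic_spec(n_per_class = 25, seed = 1))
#' ft <- build_feature_table(ts, "integrated35")
#' fit <- lnc_train(ft, "gbt", seed = 1, grid = list(max_depth = 3, eta = 0.1, nrounds = 50))
#' fit$auc
#' }
#' @export
lnc_train <- function(x, algo = c("svm_rbf", "random_forest", "gbt"),
                      seed = 1L, folds = 5L, grid = NULL, inner_folds = 5L) {
  stopifnot(inherits(x, "feature_table"))
  algo <- match.arg(algo)
  if (anyNA(x$label)) stop("every row must be labeled")
  y <- as_binary_label(x$label)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (min(table(y)) < folds) stop("need at least ", folds, " rows per class")
  if (is.null(grid)) grid <- default_grid(algo)
  X <- feature_matrix(x)
  with_seed(seed, {
    fold_id <- stratified_folds(y, folds)
    scores <- numeric(length(y))
    fold_hp <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      hp <- search_hyperparams(X[tr, , drop = FALSE], y[tr], algo, grid, inner_folds)
      fold_hp[[f]] <- hp
      m <- fit_algo(X[tr, , drop = FALSE], y[tr], algo, hp, next_seed())
      scores[!tr] <- predict_algo(m, X[!tr, , drop = FALSE])
    }
    keys <- vapply(fold_hp, function(h) paste(unlist(h), collapse = "|"), "")
    tab <- table(factor(keys, levels = unique(keys)))
    modal <- fold_hp[[match(names(tab)[which.max(tab)], keys)]]
    final <- fit_algo(X, y, algo, modal, next_seed(), importance = TRUE)
    roc <- roc_auc(y, scores)
    pr <- pr_aupr(y, scores)
    structure(list(algo = algo, hyperparams = modal, fold_hyperparams = fold_hp,
                   scores = stats::setNames(scores, x$id), labels = y,
                   fold_id = fold_id, roc = roc$points, auc = roc$auc,
                   pr = pr$points, aupr = pr$aupr,
                   importance = final$importance, fit = final,
                   seed = as.integer(seed), folds = as.integer(folds),
                   feature_set = attr(x, "feature_set"),
                   schema = feature_schema(x)),
              class = "lnc_model")
  })
}

next_seed <- function() sample.int(2147483646L, 1L)

#' Grid search for classifier hyperparameters
#'
#' Exhaustive search over the grid for the SVM; staged coordinate-wise search
#' for the tree models: parameters are optimized one at a time in the grid's
#' list order with the others held at their current values, each candidate
#' scored by stratified `folds`-fold cross-validated mean AUC. Ties keep the
#' earlier (simpler) value, and a staged search over p parameters evaluates
#' at most `sum(lengths(grid))` configurations rather than the full product.
#'
#' @inheritParams lnc_train
#' @param grid Named list of candidate value vectors (default
#'   [default_grid()]).
#' @return Named list: the selected value of each grid parameter.
#' @export
staged_grid_search <- function(x, algo = c("svm_rbf", "random_forest", "gbt"),
                               grid = NULL, seed = 1L, folds = 5L) {
  stopifnot(inherits(x, "feature_table"))
  algo <- match.arg(algo)
  if (is.null(grid)) grid <- default_grid(algo)
  y <- as_binary_label(x$label)
  with_seed(seed, search_hyperparams(feature_matrix(x), y, algo, grid, folds))
}

## worker behind staged_grid_search; consumes the caller's RNG stream
search_hyperparams <- function(X, y, algo, grid, folds) {
  if (!length(grid) || any(!lengths(grid))) stop("empty hyperparameter grid")
  for (g in grid) if (!is.numeric(g)) stop("grid values must be numeric")
  fold_id <- stratified_folds(y, folds)
  fit_seed <- next_seed()                 # one seed for all candidate fits
  score_fn <- function(hp) cv_mean_auc(X, y, algo, hp, fold_id, fit_seed)
  if (algo == "svm_rbf") {
    combos <- expand.grid(grid)
    best <- NULL; best_s <- -Inf
    for (r in seq_len(nrow(combos))) {
      hp <- lapply(combos, `[[`, r)
      s <- score_fn(hp)
      if (s > best_s + 1e-12) { best <- hp; best_s <- s }
    }
    best
  } else {
    cur <- lapply(grid, `[[`, 1L)
    cache <- new.env(parent = emptyenv())
    cached_score <- function(hp) {
      k <- paste(unlist(hp), collapse = "|")
      if (is.null(cache[[k]])) cache[[k]] <- score_fn(hp)
      cache[[k]]
    }
    for (param in names(grid)) {
      best_v <- cur[[param]]; best_s <- -Inf
      for (v in grid[[param]]) {
        hp <- cur; hp[[param]] <- v
        s <- cached_score(hp)
        if (s > best_s + 1e-12) { best_v <- v; best_s <- s }
      }
      cur[[param]] <- best_v
    }
    cur
  }
}

cv_mean_auc <- function(X, y, algo, hp, fold_id, fit_seed) {
  aucs <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    if (length(unique(y[!tr])) < 2L) return(NA_real_)
    m <- fit_algo(X[tr, , drop = FALSE], y[tr], algo, hp, fit_seed)
    roc_auc(y[!tr], predict_algo(m, X[!tr, , drop = FALSE]))$auc
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

fit_algo <- function(X, y, algo, hp, fit_seed, importance = FALSE) {
  yf <- factor(y, levels = c(0L, 1L))
  if (algo == "svm_rbf") {
    center <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0] <- 1                    # constant columns pass through
    Xs <- scale(X, center = center, scale = scl)
    fit <- e1071::svm(x = Xs, y = yf, kernel = "radial",
                      cost = hp$cost, gamma = hp$gamma, scale = FALSE)
    list(algo = algo, hp = hp, fit = fit, center = center, scale = scl,
         importance = NULL)
  } else if (algo == "random_forest") {
    fit <- ranger::ranger(x = X, y = yf, probability = TRUE,
                          num.trees = hp$num.trees,
                          max.depth = hp$max.depth,
                          min.node.size = hp$min.node.size,
                          importance = if (importance) "impurity" else "none",
                          seed = fit_seed, num.threads = 1L)
    imp <- if (importance) sort(fit$variable.importance, decreasing = TRUE)
    list(algo = algo, hp = hp, fit = fit, importance = imp)
  } else {
    params <- list(objective = "binary:logistic", max_depth = hp$max_depth,
                   eta = hp$eta, nthread = 1L, seed = fit_seed)
    fit <- xgboost::xgb.train(params = params,
                              data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
                              nrounds = hp$nrounds, verbose = 0)
    imp <- NULL
    if (importance) {
      tab <- xgboost::xgb.importance(feature_names = colnames(X), model = fit)
      imp <- stats::setNames(rep(0, ncol(X)), colnames(X))
      imp[tab$Feature] <- tab$Gain        # unused features keep gain 0
      imp <- sort(imp, decreasing = TRUE)
    }
    list(algo = algo, hp = hp, fit = fit, importance = imp)
  }
}

predict_algo <- function(m, X) {
  if (m$algo == "svm_rbf") {
    Xs <- scale(X, center = m$center, scale = m$scale)
    p <- stats::predict(m$fit, Xs, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    pos_first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1] == "1"
    stats::plogis(if (pos_first) dv[, 1] else -dv[, 1])
  } else if (m$algo == "random_forest") {
    stats::predict(m$fit, data = X, num.threads = 1L)$predictions[, "1"]
  } else {
    stats::predict(m$fit, xgboost::xgb.DMatrix(X, nthread = 1L))
  }
}

#' Gain-based feature importance of a trained tree model
#'
#' @param model An `lnc_model` fitted with `"random_forest"` or `"gbt"`.
#' @return Data frame with `feature` and `importance` (impurity/gain based,
#'   all `>= 0`), sorted descending; one row per feature column.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "lnc_model"))
  if (is.null(model$importance)) {
    stop("feature importance is unsupported for algo '", model$algo, "'")
  }
  imp <- model$importance
  missing <- setdiff(model$schema, names(imp))
  if (length(missing)) imp <- c(imp, stats::setNames(rep(0, length(missing)), missing))
  imp <- sort(imp, decreasing = TRUE)
  data.frame(feature = names(imp), importance = as.numeric(imp),
             row.names = NULL)
}

#' @export
print.lnc_model <- function(x, ...) {
  cat(sprintf("lnc_model: %s on %s (%d transcripts, %d-fold CV, seed %d)\n",
              x$algo, x$feature_set, length(x$scores), x$folds, x$seed))
  cat(sprintf("  pooled out-of-fold AUC %.4f, AUPR %.4f\n", x$auc, x$aupr))
  cat("  hyperparameters:",
      paste(names(x$hyperparams), unlist(x$hyperparams), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.lnc_model <- function(object, ...) {
  print(object)
  cat("  per-fold selections:\n")
  for (f in seq_along(object$fold_hyperparams)) {
    hp <- object$fold_hyperparams[[f]]
    cat(sprintf("    fold %d: %s\n", f,
                paste(names(hp), unlist(hp), sep = "=", collapse = ", ")))
  }
  if (!is.null(object$importance)) {
    top <- utils::head(feature_importance(object), 5L)
    cat("  top features:", paste(top$feature, collapse = ", "), "\n")
  }
  invisible(object)
}

#' Score new transcripts with a trained model
#'
#' @param object An `lnc_model`.
#' @param newdata A `feature_table` with the model's feature set, or a
#'   numeric matrix whose columns match the training schema.
#' @param ... Unused.
#' @return Numeric vector of positive-class (lncRNA) scores in `[0, 1]`.
#' @export
predict.lnc_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) feature_matrix(newdata) else as.matrix(newdata)
  if (!identical(colnames(X), object$schema)) {
    stop("newdata feature columns do not match the training schema")
  }
  sc <- predict_algo(object$fit, X)
  stats::setNames(as.numeric(sc), rownames(X))
}

#' Plot the ROC and PR curves of a trained model
#'
#' @param x An `lnc_model`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.lnc_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::plot(x$pr$recall, x$pr$precision, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Recall", ylab = "Precision",
                 main = sprintf("PR (AUPR %.4f)", x$aupr), ...)
  invisible(x)
}
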