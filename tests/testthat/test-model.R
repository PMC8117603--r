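test_that("ROC/AUC equals the pair-counting statistic, exactly", {
  r <- roc_auc(c(1, 1, 0, 0), c(.9, .8, .7, .6))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(.9, .8, .7, .6))$auc, 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)   # ties only
  expect_error(roc_auc(c(1, 1), c(.2, .3)), "both classes")

  set.seed(123)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))    # coarse rounding forces ties
    expect_equal(roc_auc(labels, scores)$auc, oracle_auc(labels, scores))
  }
})

test_that("ROC points are anchored, monotone, and AUC is rank-invariant", {
  set.seed(5)
  labels <- sample(0:1, 50, replace = TRUE, prob = c(.4, .6))
  scores <- runif(50)
  r <- roc_auc(labels, scores)
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  # strictly increasing transform leaves the ranking, hence the AUC, unchanged
  expect_equal(roc_auc(labels, exp(3 * scores))$auc, r$auc)
  expect_equal(roc_auc(labels, stats::qlogis(scores))$auc, r$auc)
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  labels <- sample(0:1, 80, replace = TRUE)
  scores <- round(runif(80), 2)
  ours <- roc_auc(labels, scores)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    labels, scores, levels = c(0, 1), direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("PR curve and step-wise area match direct computation", {
  expect_equal(pr_aupr(c(1, 1, 0, 0), c(.9, .8, .7, .6))$aupr, 1)
  toy <- pr_aupr(c(1, 0, 1, 0), c(.9, .8, .7, .6))
  expect_equal(toy$aupr, oracle_aupr(c(1, 0, 1, 0), c(.9, .8, .7, .6)))
  expect_equal(toy$aupr, 5 / 6)
  # constant scores collapse to one threshold: area = prevalence
  expect_equal(pr_aupr(c(1, 0, 0, 0), rep(0.3, 4))$aupr, 0.25)
  set.seed(321)
  for (rep in 1:30) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)
    expect_equal(pr_aupr(labels, scores)$aupr, oracle_aupr(labels, scores),
                 tolerance = 1e-12)
  }
})

sep_table <- function(n_per_class = 30, seed = 1, p = 6) {
  set.seed(seed)
  y <- rep(c("lncRNA", "PCT"), each = n_per_class)
  X <- matrix(rnorm(2 * n_per_class * p), ncol = p)
  # two-valued separating axis: every fold threshold falls strictly between
  # the classes, so pooled out-of-fold scores are perfectly ranked
  X[, 1] <- ifelse(y == "lncRNA", 4, -4)
  make_feature_table(X, y)
}

tiny_grids <- list(svm_rbf = list(cost = 1, gamma = 0.1),
                   random_forest = list(num.trees = 100, max.depth = 0,
                                        min.node.size = 2),
                   gbt = list(max_depth = 3, eta = 0.3, nrounds = 40))

test_that("a separable table yields AUC 1 for every algorithm", {
  ft <- sep_table()
  for (a in c("svm_rbf", "random_forest", "gbt")) {
    fit <- lnc_train(ft, a, seed = 1, grid = tiny_grids[[a]])
    expect_equal(fit$auc, 1, tolerance = 1e-9)
    expect_equal(fit$aupr, 1, tolerance = 1e-9)
    expect_true(all(fit$scores >= 0 & fit$scores <= 1))
    expect_length(fit$scores, nrow(ft))
  }
})

test_that("training is deterministic for a fixed table and seed", {
  ft <- sep_table(20, seed = 3)
  for (a in c("svm_rbf", "random_forest")) {
    f1 <- lnc_train(ft, a, seed = 9, grid = tiny_grids[[a]])
    f2 <- lnc_train(ft, a, seed = 9, grid = tiny_grids[[a]])
    expect_identical(f1$scores, f2$scores)
    expect_identical(f1$fold_id, f2$fold_id)
  }
})

test_that("randomly labeled data scores near chance", {
  set.seed(99)
  n <- 500
  X <- matrix(rnorm(n * 8), ncol = 8)
  y <- sample(rep(c("lncRNA", "PCT"), each = n / 2))
  fit <- lnc_train(make_feature_table(X, y), "gbt", seed = 7,
                   grid = tiny_grids$gbt)
  expect_gte(fit$auc, 0.4)
  expect_lte(fit$auc, 0.6)
})

test_that("grid search honors its contracts", {
  ft <- sep_table(15, seed = 4)
  # single-point grid is returned as-is
  hp <- staged_grid_search(ft, "gbt", grid = tiny_grids$gbt, seed = 1)
  expect_equal(hp, tiny_grids$gbt)
  hp2 <- staged_grid_search(ft, "svm_rbf", grid = tiny_grids$svm_rbf, seed = 1)
  expect_equal(hp2, tiny_grids$svm_rbf)
  # values come from the grid
  grid <- list(max_depth = c(2, 3), eta = c(0.1, 0.3), nrounds = c(20, 40))
  hp3 <- staged_grid_search(ft, "gbt", grid = grid, seed = 2)
  for (p in names(grid)) expect_true(hp3[[p]] %in% grid[[p]])
  expect_error(staged_grid_search(ft, "gbt", grid = list(max_depth = "deep")),
               "numeric")
})

test_that("staged search finds a dominant parameter value", {
  # weak-signal data: one tree scores coarsely, a full forest dominates on CV AUC
  set.seed(6)
  y <- rep(c("lncRNA", "PCT"), each = 40)
  X <- matrix(rnorm(80 * 4), ncol = 4)
  X[, 1] <- X[, 1] + ifelse(y == "lncRNA", 1, -1)
  ft <- make_feature_table(X, y)
  hp <- staged_grid_search(ft, "random_forest",
                           grid = list(num.trees = c(1, 200), max.depth = 0,
                                       min.node.size = 2), seed = 3)
  expect_equal(hp$num.trees, 200)
})

test_that("feature importance ranks the carrying feature first", {
  ft <- sep_table(30, seed = 8)
  for (a in c("random_forest", "gbt")) {
    fit <- lnc_train(ft, a, seed = 2, grid = tiny_grids[[a]])
    imp <- feature_importance(fit)
    expect_equal(nrow(imp), length(feature_schema(ft)))
    expect_true(all(imp$importance >= 0))
    expect_equal(imp$feature[1], "f1")
  }
  # constant feature carries zero gain
  ftc <- sep_table(20, seed = 10)
  ftc$f6 <- 1
  fit <- lnc_train(ftc, "gbt", seed = 2, grid = tiny_grids$gbt)
  imp <- feature_importance(fit)
  expect_equal(imp$importance[imp$feature == "f6"], 0)
  # SVM has no importance
  fsvm <- lnc_train(sep_table(15), "svm_rbf", seed = 1, grid = tiny_grids$svm_rbf)
  expect_error(feature_importance(fsvm), "unsupported")
})

test_that("prediction on new data respects the schema and score range", {
  ft <- sep_table(20, seed = 12)
  fit <- lnc_train(ft, "random_forest", seed = 4, grid = tiny_grids$random_forest)
  sc <- predict(fit, ft)
  expect_length(sc, nrow(ft))
  expect_true(all(sc >= 0 & sc <= 1))
  bad <- ft
  attr(bad, "schema") <- rev(feature_schema(ft))
  expect_error(predict(fit, bad), "schema")
})

test_that("degenerate tables are rejected", {
  ft <- sep_table(10)
  one_class <- ft[ft$label == "PCT", ]
  class(one_class) <- class(ft)
  attr(one_class, "schema") <- feature_schema(ft)
  attr(one_class, "feature_set") <- "integrated35"
  expect_error(lnc_train(one_class, "gbt"), "both classes")
  expect_error(lnc_train(ft, "gbt", folds = 20), "rows per class")
})
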