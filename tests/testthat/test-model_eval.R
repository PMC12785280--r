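test_that("stratified splitting reproduces the 45-sample test layout", {
  tab <- data.frame(record_id = sprintf("r%03d", 1:224),
                    x = rnorm(224),
                    label = rep(c(0L, 1L), each = 112))
  sp <- stratified_split(tab, 0.2, seed = 42)
  expect_identical(nrow(sp$test), 45L)
  expect_identical(nrow(sp$train), 179L)
  # largest-remainder tie goes to the class listed first (normal): 23 vs 22
  expect_identical(sum(sp$test$label == 0L), 23L)
  expect_identical(sum(sp$test$label == 1L), 22L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  # determinism
  sp2 <- stratified_split(tab, 0.2, seed = 42)
  expect_identical(sp2$test_idx, sp$test_idx)
  # empty test at fraction 0
  sp0 <- stratified_split(tab, 0, seed = 1)
  expect_identical(nrow(sp0$test), 0L)
  expect_identical(nrow(sp0$train), 224L)
  expect_error(stratified_split(data.frame(label = c(0L, 0L)), 0.5, 1),
               class = "pcg_single_class")
})

test_that("hyperparameter grids match the stated search spaces", {
  expect_identical(nrow(hyper_grid("svm_rbf")), 16L)  # 4 x 4
  expect_identical(nrow(hyper_grid("logreg")), 1L)
  expect_identical(nrow(hyper_grid("dtree")), 180L)   # 3 x 10 x 6
  expect_identical(nrow(hyper_grid("rforest")), 72L)  # 3 x 8 x 3
  expect_setequal(unique(hyper_grid("svm_rbf")$gamma), c("scale", "0.01", "0.1", "1"))
  expect_setequal(unique(hyper_grid("rforest")$num_trees), c(200L, 500L, 1000L))
  expect_error(hyper_grid("mlp"), class = "pcg_bad_algorithm")
})

test_that("grid search returns in-grid parameters and separates separable data", {
  set.seed(5)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4)
  x[, 1] <- x[, 1] + 6 * y  # linearly separable by construction
  colnames(x) <- paste0("f", 1:4)
  tab <- cbind(as.data.frame(x), data.frame(label = y))
  for (alg in c("svm_rbf", "logreg", "dtree", "rforest")) {
    fit <- grid_search_train(tab, alg, seed = 7)
    expect_s3_class(fit, "pcg_fit")
    expect_gte(fit$cv_score, 0.9)
    grid <- hyper_grid(alg)
    expect_true(nrow(merge(fit$best_params, grid)) >= 1)  # best params in grid
    pred <- pcgclass:::predict_clf(fit$model, x)
    expect_gte(mean(pred$class == y), 0.95)
  }
  # SVM achieves perfect training accuracy at some grid point
  fit <- pcgclass:::fit_clf("svm_rbf", list(cost = 100, gamma = "scale"), x, y)
  expect_identical(pcgclass:::predict_clf(fit, x)$class, y)
})

test_that("random-forest tree-nesting CV scores match direct per-config fits", {
  set.seed(31)
  n <- 50
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5)
  x[, 2] <- x[, 2] + 2 * y
  colnames(x) <- paste0("f", 1:5)
  folds <- pcgclass:::stratified_folds(y, 5L, seed = 4)
  fold_idx <- lapply(1:5, function(f) list(tr = which(folds != f), va = which(folds == f)))
  grid <- expand.grid(num_trees = c(200L, 1000L), max_depth = 8L, sampling = "sqrt",
                      stringsAsFactors = FALSE)
  fast <- pcgclass:::rf_grid_cv(grid, x, y, fold_idx, seed = 99)
  # direct oracle: grow each forest separately with the same seeds and count
  direct <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(seq_along(fold_idx), function(fi) {
      f <- fold_idx[[fi]]
      m <- ranger::ranger(x = x[f$tr, ], y = factor(y[f$tr], levels = c(0, 1)),
                          num.trees = 1000L, max.depth = 8L,
                          mtry = pcgclass:::resolve_mtry("sqrt", 5L),
                          num.threads = 1L, verbose = FALSE, oob.error = FALSE,
                          seed = 99 + 1)
      votes <- predict(m, data = x[f$va, ], predict.all = TRUE,
                       num.threads = 1L)$predictions
      lev1 <- which(m$forest$levels == "1")
      pred <- as.integer(rowMeans(votes[, seq_len(grid$num_trees[i]), drop = FALSE] == lev1) > 0.5)
      mean(pred == y[f$va])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(fast, direct, tolerance = 1e-12)
})

test_that("confusion counts match brute-force enumeration", {
  y <- c(1L, 0L, 1L, 1L, 0L, 0L)
  p <- c(1L, 1L, 0L, 1L, 0L, 1L)
  cc <- confusion(y, p)
  brute <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (i in seq_along(y)) {
    k <- if (y[i] == 1L && p[i] == 1L) "TP" else if (y[i] == 0L && p[i] == 1L) "FP"
         else if (y[i] == 1L) "FN" else "TN"
    brute[k] <- brute[k] + 1L
  }
  expect_identical(unclass(cc), brute)
  expect_identical(sum(cc), length(y))
  same <- confusion(y, y)
  expect_identical(same[["FP"]] + same[["FN"]], 0L)
  allpos <- confusion(y, rep(1L, 6))
  expect_identical(allpos[["TN"]] + allpos[["FN"]], 0L)
  expect_error(confusion(y, p[1:3]), class = "pcg_shape_mismatch")
  expect_error(confusion(c(0L, 2L), c(0L, 1L)), class = "pcg_bad_label")
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(8)
  for (i in 1:200) {
    cc <- c(TP = sample(0:30, 1), FP = sample(0:30, 1),
            FN = sample(0:30, 1), TN = sample(1:30, 1))
    m <- suppressWarnings(compute_metrics(cc))
    expect_equal(m[["accuracy"]], (cc[["TP"]] + cc[["TN"]]) / sum(cc))
    if (cc[["TP"]] + cc[["FN"]] > 0)
      expect_equal(m[["recall"]] + cc[["FN"]] / (cc[["TP"]] + cc[["FN"]]), 1)
    if (cc[["TN"]] + cc[["FP"]] > 0)
      expect_equal(m[["specificity"]] + cc[["FP"]] / (cc[["FP"]] + cc[["TN"]]), 1)
    if (m[["precision"]] + m[["recall"]] > 0)
      expect_equal(m[["f1"]],
                   2 * m[["precision"]] * m[["recall"]] / (m[["precision"]] + m[["recall"]]))
    expect_true(all(m >= 0 & m <= 1))
  }
  perfect <- compute_metrics(c(TP = 10L, FP = 0L, FN = 0L, TN = 12L))
  expect_equal(unname(perfect), rep(1, 5))
  expect_warning(compute_metrics(c(TP = 0L, FP = 0L, FN = 3L, TN = 3L)), "precision")
})

test_that("ROC/AUC equals the Mann-Whitney statistic and is rank-invariant", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0L, 0L, 1L, 1L))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c(0L, 1L), 3))$auc, 0.5)
  set.seed(13)
  for (i in 1:20) {
    y <- rep(c(0L, 1L), each = 10)
    s <- rnorm(20)
    r <- roc_auc(s, y)
    # oracle: all-pairs comparison count (ties count 1/2)
    pos <- s[y == 1L]; neg <- s[y == 0L]
    u <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
    expect_equal(r$auc, u / 100, tolerance = 1e-12)
    # invariance under strictly monotone transform
    expect_equal(roc_auc(exp(s / 2), y)$auc, r$auc, tolerance = 1e-12)
    # monotone curve from (0,0) to (1,1)
    expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
    expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  }
  expect_error(roc_auc(1:4, rep(1L, 4)), class = "pcg_single_class")
  expect_error(roc_auc(c(1, NA, 3), c(0L, 1L, 0L)), class = "pcg_bad_scores")
})

test_that("the experiment plan enumerates 8 models per dataset, 120 total", {
  plan <- experiment_plan()
  expect_identical(nrow(plan), 120L)
  expect_identical(as.integer(table(plan$dataset_id)), rep(8L, 15))
  expect_identical(nrow(unique(plan[c("selector", "algorithm")])), 8L)
})

test_that("a reduced experiment run is reproducible and well-formed", {
  recs <- small_corpus(10, 10)
  rep1 <- run_experiment(recs, seed = 7, datasets = 2L)
  expect_identical(nrow(rep1), 8L)
  expect_true(all(c("model", "selector", "n_features", "dataset", "accuracy",
                    "precision", "recall", "specificity", "f1", "auc") %in% names(rep1)))
  metrics <- as.matrix(rep1[c("accuracy", "precision", "recall", "specificity", "f1", "auc")])
  expect_true(all(metrics >= 0 & metrics <= 1))
  expect_identical(rep1$tp + rep1$fp + rep1$fn + rep1$tn, rep(4L, 8L))
  rep2 <- run_experiment(recs, seed = 7, datasets = 2L)
  expect_identical(rep1, rep2)  # bitwise-identical rerun
})
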