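#' Stratified train/test split
#'
#' The test set holds `round(test_fraction * N)` rows, allocated to classes
#' by largest-remainder rounding of the per-class proportions (ties toward
#' the class listed first, i.e. normal); rows are drawn without replacement
#' under the seed, and both partitions keep the original row order.
#'
#' @param table Data frame with a `label` column (0/1).
#' @param test_fraction Fraction of rows held out for testing.
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (data frames) and the row
#'   indices `train_idx`, `test_idx`.
#' @export
stratified_split <- function(table, test_fraction = 0.2, seed = 42L) {
  y <- table$label
  classes <- sort(unique(y))
  if (test_fraction > 0 && (length(classes) < 2L || any(table(y) < 2L)))
    stop(pcg_error("pcg_single_class", "both classes need at least 2 rows"))
  n_test <- round(test_fraction * nrow(table))
  exact <- vapply(classes, function(c) test_fraction * sum(y == c), numeric(1))
  base <- floor(exact)
  rem <- n_test - sum(base)
  if (rem > 0) {
    ord <- order(-(exact - base), seq_along(classes))  # largest remainder, then class order
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  test_idx <- integer(0)
  with_seed(seed, {
    for (i in seq_along(classes)) {
      idx <- which(y == classes[i])
      if (base[i] > 0) test_idx <- c(test_idx, sample(idx, base[i]))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(table)), test_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

#' Hyperparameter grids for the four classifiers
#'
#' SVM (RBF): cost in \{0.1, 1, 10, 100\} by gamma in \{scale, 0.01, 0.1,
#' 1\}. Logistic regression: a single L2-penalized configuration (C = 1).
#' Decision tree: splitting criterion in \{gini, entropy, log_loss\}, depth
#' 3-12, minimum leaf size 1-6. Random forest: 200/500/1000 trees, depth
#' 5-12, feature sampling sqrt/log2/0.5.
#'
#' @param algorithm One of `"svm_rbf"`, `"logreg"`, `"dtree"`, `"rforest"`.
#' @return Data frame of configurations (one row each).
#' @export
hyper_grid <- function(algorithm) {
  switch(algorithm,
    svm_rbf = expand.grid(cost = c(0.1, 1, 10, 100),
                          gamma = c("scale", "0.01", "0.1", "1"),
                          stringsAsFactors = FALSE),
    logreg = data.frame(C = 1),
    dtree = expand.grid(criterion = c("gini", "entropy", "log_loss"),
                        max_depth = 3:12, min_leaf = 1:6,
                        stringsAsFactors = FALSE),
    rforest = expand.grid(num_trees = c(200L, 500L, 1000L), max_depth = 5:12,
                          sampling = c("sqrt", "log2", "0.5"),
                          stringsAsFactors = FALSE),
    stop(pcg_error("pcg_bad_algorithm", sprintf("unknown algorithm '%s'", algorithm))))
}

#' Exhaustive grid search with stratified cross-validation
#'
#' Every configuration in [hyper_grid()] is scored by mean accuracy over
#' stratified k-fold cross-validation on the training data; the best
#' configuration (first one on ties, in grid enumeration order) is refitted
#' on the full training split.
#'
#' Two exact shortcuts keep the search cheap: decision-tree configurations
#' that map to the same rpart fit (entropy and log-loss both use the
#' information criterion) are fitted once and share their score, and the
#' random-forest tree-count axis is scored from the first 200/500/1000 trees
#' of a single 1000-tree forest per depth/sampling/fold (trees are i.i.d.
#' given the data, so the truncated forest is exactly a forest of that
#' size).
#'
#' @param train Feature table with a `label` column, already standardized.
#' @param algorithm One of `"svm_rbf"`, `"logreg"`, `"dtree"`, `"rforest"`.
#' @param cv_folds Number of CV folds.
#' @param seed Integer seed (folds and forest randomness).
#' @return List of class `pcg_fit`: fitted `model` (a `pcg_clf`),
#'   `best_params` (one-row data frame), `cv_score`, `cv_scores` (per
#'   config), `algorithm`, `features`.
#' @export
grid_search_train <- function(train, algorithm, cv_folds = 5L, seed = 42L) {
  feats <- feature_columns(train)
  x <- as.matrix(train[feats])
  y <- as.integer(train$label)
  grid <- hyper_grid(algorithm)
  folds <- stratified_folds(y, cv_folds, seed)
  fold_idx <- lapply(seq_len(cv_folds), function(f)
    list(tr = which(folds != f), va = which(folds == f)))

  scores <- if (algorithm == "rforest") {
    rf_grid_cv(grid, x, y, fold_idx, seed)
  } else {
    cache <- new.env(parent = emptyenv())
    vapply(seq_len(nrow(grid)), function(i) {
      params <- as.list(grid[i, , drop = FALSE])
      key <- if (algorithm == "dtree")
        paste(rpart_split(params$criterion), params$max_depth, params$min_leaf)
      else paste(unlist(params), collapse = "|")
      if (!is.null(cache[[key]])) return(cache[[key]])
      acc <- mean(vapply(fold_idx, function(fi) {
        fit <- fit_clf(algorithm, params, x[fi$tr, , drop = FALSE], y[fi$tr],
                       seed = seed)
        mean(predict_clf(fit, x[fi$va, , drop = FALSE])$class == y[fi$va])
      }, numeric(1)))
      cache[[key]] <- acc
      acc
    }, numeric(1))
  }

  best <- which.max(scores)  # first maximum on ties
  best_params <- as.list(grid[best, , drop = FALSE])
  model <- fit_clf(algorithm, best_params, x, y, seed = seed,
                   probability = algorithm == "rforest")
  structure(list(model = model, best_params = grid[best, , drop = FALSE],
                 cv_score = scores[best], cv_scores = scores,
                 algorithm = algorithm, features = feats),
            class = "pcg_fit")
}

## CV accuracies for the whole random-forest grid: one 1000-tree forest per
## (max_depth, sampling, fold); per-tree validation votes are accumulated so
## the 200/500/1000-tree configurations are scored exactly.
rf_grid_cv <- function(grid, x, y, fold_idx, seed) {
  tree_counts <- sort(unique(grid$num_trees))
  combos <- unique(grid[c("max_depth", "sampling")])
  scores <- numeric(nrow(grid))
  for (ci in seq_len(nrow(combos))) {
    depth <- combos$max_depth[ci]
    sampling <- combos$sampling[ci]
    acc <- stats::setNames(numeric(length(tree_counts)), tree_counts)
    for (fi in fold_idx) {
      m <- ranger::ranger(x = x[fi$tr, , drop = FALSE],
                          y = factor(y[fi$tr], levels = c(0L, 1L)),
                          num.trees = max(tree_counts), max.depth = depth,
                          mtry = resolve_mtry(sampling, ncol(x)),
                          num.threads = 1L, verbose = FALSE, oob.error = FALSE,
                          seed = seed + ci)
      votes <- stats::predict(m, data = x[fi$va, , drop = FALSE],
                              predict.all = TRUE, num.threads = 1L)$predictions
      lev1 <- which(m$forest$levels == "1")
      is1 <- votes == lev1
      for (tc in tree_counts) {
        pred <- as.integer(rowMeans(is1[, seq_len(tc), drop = FALSE]) > 0.5)
        acc[[as.character(tc)]] <- acc[[as.character(tc)]] +
          mean(pred == y[fi$va]) / length(fold_idx)
      }
    }
    sel <- grid$max_depth == depth & grid$sampling == sampling
    scores[sel] <- acc[as.character(grid$num_trees[sel])]
  }
  scores
}

#' Confusion counts for binary predictions
#'
#' Abnormal (label 1) is the positive class.
#'
#' @param y_true,y_pred Integer 0/1 vectors of equal length.
#' @return Named integer vector of class `pcg_confusion`:
#'   `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop(pcg_error("pcg_shape_mismatch", "y_true and y_pred differ in length"))
  if (!all(c(y_true, y_pred) %in% c(0L, 1L)))
    stop(pcg_error("pcg_bad_label", "labels must be binary 0/1"))
  structure(c(TP = sum(y_true == 1L & y_pred == 1L),
              FP = sum(y_true == 0L & y_pred == 1L),
              FN = sum(y_true == 1L & y_pred == 0L),
              TN = sum(y_true == 0L & y_pred == 0L)),
            class = "pcg_confusion")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, recall (sensitivity)
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1 (harmonic mean of precision
#' and recall). A zero denominator yields 0 with a warning.
#'
#' @param cc Counts from [confusion()] (or a named vector with `TP`, `FP`,
#'   `FN`, `TN`).
#' @return Named numeric vector: `accuracy`, `precision`, `recall`,
#'   `specificity`, `f1`.
#' @export
compute_metrics <- function(cc) {
  tp <- cc[["TP"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]; tn <- cc[["TN"]]
  n <- tp + fp + fn + tn
  if (n == 0) stop(pcg_error("pcg_empty_counts", "empty confusion counts"))
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(sprintf("%s undefined (zero denominator); returning 0", what)); 0 }
    else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  c(accuracy = (tp + tn) / n,
    precision = precision,
    recall = recall,
    specificity = safe_div(tn, tn + fp, "specificity"),
    f1 = if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall))
}

#' ROC curve and area under it
#'
#' Thresholds are swept over the unique scores (ties cross simultaneously);
#' the curve runs from (0, 0) to (1, 1) and the AUC is computed by the
#' trapezoidal rule, which equals the Mann-Whitney U statistic divided by
#' `n1 * n0`.
#'
#' @param scores Finite continuous decision values, larger = more abnormal.
#' @param y_true Integer 0/1 labels (both classes present).
#' @return List of class `pcg_roc`: `points` (data frame `fpr`, `tpr`),
#'   `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  y_true <- as.integer(y_true)
  if (!all(is.finite(scores)))
    stop(pcg_error("pcg_bad_scores", "scores must be finite"))
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L)
    stop(pcg_error("pcg_single_class", "both classes required for a ROC curve"))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y_true[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last element of each tie group
  tpr <- c(0, cumsum(y == 1L)[keep] / n1)
  fpr <- c(0, cumsum(y == 0L)[keep] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "pcg_roc")
}

## ---- the full experiment --------------------------------------------------

#' Enumerate the model grid of the full experiment
#'
#' @param datasets Dataset ids (default all 15).
#' @param selectors Feature selectors.
#' @param algorithms Classifier algorithms.
#' @return Data frame with one row per model (15 x 2 x 4 = 120 by default).
#' @export
experiment_plan <- function(datasets = 1:15,
                            selectors = c("forward", "boruta"),
                            algorithms = c("svm_rbf", "logreg", "dtree", "rforest")) {
  plan <- expand.grid(algorithm = algorithms, selector = selectors,
                      dataset_id = datasets, stringsAsFactors = FALSE)
  plan[order(plan$dataset_id), c("dataset_id", "selector", "algorithm")]
}

derive_seed <- function(seed, dataset_id, selector, algorithm) {
  sel <- match(selector, c("forward", "boruta"))
  alg <- match(algorithm, c(.algorithms, "any"))
  as.integer((as.numeric(seed) * 48271 + dataset_id * 10007 +
                sel * 101 + alg * 7) %% 2147483647) + 1L
}

#' Load and preprocess a corpus from a manifest
#'
#' Reads each WAV, resamples to `target_fs`, peak-normalizes and
#' standardizes the duration; labels come from the manifest.
#'
#' @param man A [pcg_manifest()] whose `path` column points at WAV files.
#' @param target_fs Analysis sampling rate (Hz).
#' @param policy A [duration_policy()].
#' @return List of preprocessed [pcg_recording()]s in manifest order.
#' @export
load_corpus <- function(man, target_fs = 4000, policy = duration_policy()) {
  lapply(seq_len(nrow(man)), function(i) {
    rec <- read_wav(man$path[i], record_id = man$record_id[i], label = man$label[i])
    standardize_duration(peak_normalize(resample_recording(rec, target_fs)), policy)
  })
}

#' Run the full classification experiment
#'
#' For every dataset of the hybrid grid and each feature selector and
#' classifier: stratified 80/20 split (shared across datasets), z-score
#' standardization fitted on training rows, feature selection on training
#' rows only, exhaustive grid search with 5-fold CV, and held-out test
#' evaluation (confusion counts, the five metrics, ROC/AUC). A failed stage
#' aborts that model's row with a message; other rows continue. All
#' randomness derives from `seed`, so a rerun is identical.
#'
#' Forward selection wraps the fast logistic scorer for every classifier
#' family (so one forward pass per dataset is shared by the four
#' classifiers); Boruta is likewise run once per dataset.
#'
#' @param recordings List of preprocessed, binarized-label
#'   [pcg_recording()]s (see [load_corpus()]), or a [pcg_manifest()] to load.
#' @param seed Master integer seed.
#' @param datasets Dataset ids to run (default all 15).
#' @param selectors Feature selectors to run.
#' @param algorithms Classifier algorithms to run.
#' @param test_fraction Held-out test fraction.
#' @param cv_folds CV folds for selection and grid search.
#' @param verbose Print per-model progress lines.
#' @return Data frame with one row per model: `model`, `selector`,
#'   `n_features`, `dataset`, `accuracy`, `precision`, `recall`,
#'   `specificity`, `f1`, `auc`, plus confusion counts `tp`, `fp`, `fn`,
#'   `tn` and the chosen hyperparameters (`best_params`).
#' @export
run_experiment <- function(recordings, seed = 42L, datasets = 1:15,
                           selectors = c("forward", "boruta"),
                           algorithms = c("svm_rbf", "logreg", "dtree", "rforest"),
                           test_fraction = 0.2, cv_folds = 5L, verbose = FALSE) {
  if (inherits(recordings, "pcg_manifest"))
    recordings <- load_corpus(recordings)
  labels <- vapply(recordings, function(r) r$label, character(1))
  split <- stratified_split(data.frame(label = as.integer(labels == "abnormal")),
                            test_fraction, seed = derive_seed(seed, 0L, "forward", "any"))

  # feature caches shared across datasets
  mf_cache <- new.env(parent = emptyenv())
  wv_cache <- new.env(parent = emptyenv())
  grid <- dataset_grid()
  rows <- list()
  for (d in datasets) {
    spec <- grid[grid$dataset_id == d, ]
    mk <- as.character(spec$n_mfcc)
    if (is.null(mf_cache[[mk]]))
      mf_cache[[mk]] <- do.call(rbind, lapply(recordings, mfcc_features,
                                              n_mfcc = spec$n_mfcc))
    if (is.null(wv_cache[[spec$family]]))
      wv_cache[[spec$family]] <- do.call(rbind, lapply(
        recordings, wavelet_features,
        family = daubechies_filters(as.integer(sub("db", "", spec$family)))))
    table <- data.frame(record_id = vapply(recordings, function(r) r$record_id, character(1)),
                        mf_cache[[mk]], wv_cache[[spec$family]],
                        label = as.integer(labels == "abnormal"),
                        stringsAsFactors = FALSE, check.names = FALSE)
    train <- table[split$train_idx, , drop = FALSE]
    test <- table[split$test_idx, , drop = FALSE]
    zp <- zscore_fit(train)
    train <- zscore_apply(zp, train)
    test <- zscore_apply(zp, test)

    sels <- list()
    if ("forward" %in% selectors)
      sels$forward <- forward_select(train, estimator = "logreg", cv_folds = cv_folds,
                                     seed = derive_seed(seed, d, "forward", "any"))
    if ("boruta" %in% selectors)
      sels$boruta <- boruta_select(train, seed = derive_seed(seed, d, "boruta", "any"))

    for (sel_name in selectors) {
      sel <- sels[[sel_name]]
      for (alg in algorithms) {
        row <- tryCatch({
          if (length(sel$selected) == 0L)
            stop(pcg_error("pcg_empty_selection", "selector retained no features"))
          cols <- c(sel$selected, "label")
          mseed <- derive_seed(seed, d, sel_name, alg)
          fit <- grid_search_train(train[cols], alg, cv_folds = cv_folds, seed = mseed)
          pred <- predict_clf(fit$model, as.matrix(test[sel$selected]))
          cc <- confusion(test$label, pred$class)
          met <- compute_metrics(cc)
          roc <- roc_auc(pred$score, test$label)
          data.frame(model = alg, selector = sel_name,
                     n_features = length(sel$selected), dataset = d,
                     accuracy = met[["accuracy"]], precision = met[["precision"]],
                     recall = met[["recall"]], specificity = met[["specificity"]],
                     f1 = met[["f1"]], auc = roc$auc,
                     tp = cc[["TP"]], fp = cc[["FP"]], fn = cc[["FN"]], tn = cc[["TN"]],
                     best_params = paste(names(fit$best_params),
                                         unlist(fit$best_params),
                                         sep = "=", collapse = ","),
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          message(sprintf("model (dataset %d, %s, %s) failed: %s",
                          d, sel_name, alg, conditionMessage(e)))
          NULL
        })
        if (!is.null(row)) {
          rows[[length(rows) + 1L]] <- row
          if (verbose)
            message(sprintf("dataset %2d %-7s %-7s acc=%.4f auc=%.4f (%d features)",
                            d, sel_name, alg, row$accuracy, row$auc, row$n_features))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
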