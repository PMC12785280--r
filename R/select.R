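#' Greedy forward feature selection with cross-validated F1-macro scoring
#'
#' Starting from the empty set, the feature whose addition gives the highest
#' mean F1-macro over stratified k-fold cross-validation is added at each
#' step (ties broken toward the lower column index). Subset sizes on the
#' `sizes` grid are recorded; the final subset is the recorded size with the
#' highest CV score, ties broken toward the smaller size. Only the rows of
#' `train` are ever consulted.
#'
#' @param train Feature table with a `label` column (0/1).
#' @param estimator Wrapped classifier family used for scoring: `"logreg"`
#'   (default, a fast unpenalized logistic fit), `"svm_rbf"`, `"dtree"` or
#'   `"rforest"`.
#' @param sizes Candidate subset sizes (default 5, 10, 15, 20, 25).
#' @param cv_folds Number of stratified CV folds.
#' @param seed Integer seed fixing fold assignment (and any estimator
#'   randomness).
#' @return A list of class `pcg_selection`: `method`, `estimator`,
#'   `selected` (ordered feature names), `path` (full greedy order),
#'   `size_scores`, `best_size`, `seed`.
#' @export
forward_select <- function(train, estimator = "logreg",
                           sizes = c(5L, 10L, 15L, 20L, 25L),
                           cv_folds = 5L, seed = 42L) {
  feats <- feature_columns(train)
  x <- as.matrix(train[feats])
  y <- as.integer(train$label)
  p <- ncol(x)
  sizes <- sort(unique(as.integer(sizes)))
  sizes <- sizes[sizes <= p]
  if (length(sizes) == 0L)
    stop(pcg_error("pcg_too_few_features", "fewer features than every requested size"))
  if (length(unique(y)) < 2L)
    stop(pcg_error("pcg_single_class", "training data has a single class"))
  folds <- stratified_folds(y, cv_folds, seed)
  fold_idx <- lapply(seq_len(cv_folds), function(f)
    list(tr = which(folds != f), va = which(folds == f)))

  selected <- integer(0)
  remaining <- seq_len(p)
  size_scores <- stats::setNames(rep(NA_real_, length(sizes)), sizes)
  max_size <- max(sizes)
  for (step in seq_len(max_size)) {
    best_score <- -Inf
    best_j <- NA_integer_
    for (j in remaining) {
      cols <- c(selected, j)
      sc <- 0
      for (f in seq_len(cv_folds)) {
        fi <- fold_idx[[f]]
        pred <- light_fit_predict(estimator,
                                  x[fi$tr, cols, drop = FALSE], y[fi$tr],
                                  x[fi$va, cols, drop = FALSE],
                                  seed = seed + f)
        sc <- sc + f1_macro(y[fi$va], pred)
      }
      sc <- sc / cv_folds
      if (sc > best_score) { best_score <- sc; best_j <- j }
    }
    selected <- c(selected, best_j)
    remaining <- setdiff(remaining, best_j)
    if (step %in% sizes) size_scores[[as.character(step)]] <- best_score
  }
  best_size <- sizes[[which.max(size_scores)]]  # which.max takes first maximum
  structure(list(method = "forward", estimator = estimator,
                 selected = feats[selected[seq_len(best_size)]],
                 path = feats[selected],
                 size_scores = size_scores, best_size = best_size, seed = seed),
            class = "pcg_selection")
}

#' Boruta-style all-relevant feature selection
#'
#' Each iteration appends a "shadow" copy of every feature with its rows
#' independently permuted, fits a random forest, and counts a hit for every
#' real feature whose impurity importance exceeds the maximum shadow
#' importance. After each iteration, features are confirmed or rejected by
#' binomial tail tests of their hit counts at level `alpha`, using the
#' reference two-step correction: Benjamini-Hochberg across the
#' still-undecided features combined with a Bonferroni bound over the
#' repeated per-iteration testing (`alpha / iteration`). Features still
#' tentative at `max_iter` are resolved by comparing their median importance history
#' to the median of the shadow maxima ("rough fix"); rough-fixed features
#' enter the selection but keep the `tentative` decision.
#'
#' @param train Feature table with a `label` column (0/1).
#' @param n_estimators Floor on the number of trees; the count is scaled up
#'   with the (real + shadow) feature count.
#' @param max_iter Maximum number of iterations.
#' @param alpha Significance level of the binomial tests.
#' @param seed Integer seed for permutations and forests.
#' @return A list of class `pcg_selection`: `method`, `selected`,
#'   `decision` (named `confirmed`/`rejected`/`tentative`), `hits`,
#'   `n_iter`, `seed`.
#' @export
boruta_select <- function(train, n_estimators = 100L, max_iter = 100L,
                          alpha = 0.05, seed = 42L) {
  feats <- feature_columns(train)
  x <- as.matrix(train[feats])
  y <- factor(as.integer(train$label), levels = c(0L, 1L))
  p <- ncol(x)
  if (p < 2L) stop(pcg_error("pcg_too_few_features", "need at least 2 features"))
  if (length(unique(y)) < 2L)
    stop(pcg_error("pcg_single_class", "training data has a single class"))
  if (all(apply(x, 2, function(col) length(unique(col)) == 1L)))
    stop(pcg_error("pcg_degenerate_features", "all features are constant"))

  status <- stats::setNames(rep("tentative", p), feats)
  hits <- stats::setNames(integer(p), feats)
  imp_hist <- matrix(NA_real_, nrow = max_iter, ncol = p,
                     dimnames = list(NULL, feats))
  shadow_max_hist <- numeric(0)
  n_trees <- max(n_estimators, 2L * p)
  n_iter <- 0L

  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      n_iter <- iter
      shadow <- apply(x, 2, sample)
      colnames(shadow) <- paste0(".shadow_", feats)
      fit <- ranger::ranger(x = cbind(x, shadow), y = y,
                            num.trees = n_trees, importance = "impurity",
                            num.threads = 1L, verbose = FALSE, oob.error = FALSE,
                            seed = sample.int(.Machine$integer.max, 1L))
      imp <- fit$variable.importance
      imp_real <- imp[feats]
      shadow_max <- max(imp[colnames(shadow)])
      shadow_max_hist <- c(shadow_max_hist, shadow_max)
      imp_hist[iter, ] <- imp_real
      und <- names(status)[status == "tentative"]
      hits[und] <- hits[und] + (imp_real[und] > shadow_max)
      # two-step correction: BH across undecided features, and a Bonferroni
      # bound over the repeated testing across iterations
      p_acc <- stats::pbinom(hits[und] - 1L, iter, 0.5, lower.tail = FALSE)
      p_rej <- stats::pbinom(hits[und], iter, 0.5)
      acc <- stats::p.adjust(p_acc, "BH") < alpha & p_acc <= alpha / iter
      rej <- stats::p.adjust(p_rej, "BH") < alpha & p_rej <= alpha / iter
      status[und[acc]] <- "confirmed"
      status[und[rej & !acc]] <- "rejected"
      if (!any(status == "tentative")) break
    }
  })

  selected <- names(status)[status == "confirmed"]
  tent <- names(status)[status == "tentative"]
  if (length(tent)) {
    med_shadow <- stats::median(shadow_max_hist)
    fixed <- tent[vapply(tent, function(f)
      stats::median(imp_hist[seq_len(n_iter), f]) > med_shadow, logical(1))]
    selected <- c(selected, fixed)
  }
  structure(list(method = "boruta", selected = selected, decision = status,
                 hits = hits, n_iter = n_iter, seed = seed),
            class = "pcg_selection")
}

#' Write a selection report as JSON
#'
#' @param sel A `pcg_selection` from [forward_select()] or [boruta_select()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(sel, path) {
  stopifnot(inherits(sel, "pcg_selection"))
  jsonlite::write_json(sel[setdiff(names(sel), "path")], path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
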