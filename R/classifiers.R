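## Internal classifier layer: uniform fit/predict over the four supported
## algorithms. Labels are integer 0 (normal) / 1 (abnormal); scores are
## oriented so that larger means more abnormal.

.algorithms <- c("svm_rbf", "logreg", "dtree", "rforest")

resolve_gamma <- function(gamma, x) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(x))
    if (!is.finite(v) || v == 0) v <- 1
    1 / (ncol(x) * v)
  } else as.numeric(gamma)
}

resolve_mtry <- function(sampling, p) {
  m <- switch(as.character(sampling),
              sqrt = floor(sqrt(p)),
              log2 = floor(log2(p)),
              max(1, floor(as.numeric(sampling) * p)))
  max(1L, min(p, as.integer(m)))
}

rpart_split <- function(criterion) {
  # rpart offers gini and information; entropy and log-loss are both the
  # information (entropy) criterion.
  if (criterion == "gini") "gini" else "information"
}

fit_clf <- function(algorithm, params, x, y, seed = 42L, probability = FALSE) {
  x <- as.matrix(x)
  y <- as.integer(y)
  fit <- switch(algorithm,
    svm_rbf = {
      m <- e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "radial",
                      cost = params$cost, gamma = resolve_gamma(params$gamma, x),
                      scale = FALSE, fitted = FALSE)
      list(model = m)
    },
    logreg = {
      xx <- if (ncol(x) == 1L) cbind(x, .pad = 0) else x
      m <- glmnet::glmnet(xx, factor(y, levels = c(0L, 1L)), family = "binomial",
                          alpha = 0, lambda = 1 / (nrow(xx) * params$C),
                          standardize = FALSE, thresh = 1e-10, maxit = 1e6)
      list(model = m, padded = ncol(x) == 1L)
    },
    dtree = {
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0L, 1L))
      m <- rpart::rpart(.y ~ ., data = df, method = "class",
                        parms = list(split = rpart_split(params$criterion)),
                        control = rpart::rpart.control(
                          maxdepth = params$max_depth, minbucket = params$min_leaf,
                          minsplit = 2L, cp = 0, xval = 0))
      list(model = m)
    },
    rforest = {
      m <- ranger::ranger(x = x, y = factor(y, levels = c(0L, 1L)),
                          num.trees = params$num_trees, max.depth = params$max_depth,
                          mtry = resolve_mtry(params$sampling, ncol(x)),
                          probability = probability, num.threads = 1L,
                          verbose = FALSE, oob.error = FALSE, seed = seed)
      list(model = m, probability = probability)
    },
    stop(pcg_error("pcg_bad_algorithm", sprintf("unknown algorithm '%s'", algorithm))))
  fit$algorithm <- algorithm
  fit$features <- colnames(x)
  class(fit) <- "pcg_clf"
  fit
}

predict_clf <- function(fit, x) {
  x <- as.matrix(x)
  switch(fit$algorithm,
    svm_rbf = {
      pr <- stats::predict(fit$model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      score <- if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
      list(class = as.integer(as.character(pr)), score = as.numeric(score))
    },
    logreg = {
      xx <- if (isTRUE(fit$padded)) cbind(x, .pad = 0) else x
      eta <- as.numeric(stats::predict(fit$model, xx, type = "link"))
      list(class = as.integer(eta > 0), score = eta)
    },
    dtree = {
      p1 <- stats::predict(fit$model, as.data.frame(x), type = "prob")[, "1"]
      list(class = as.integer(p1 > 0.5), score = as.numeric(p1))
    },
    rforest = {
      if (isTRUE(fit$probability)) {
        p1 <- stats::predict(fit$model, data = x, num.threads = 1L)$predictions[, "1"]
        list(class = as.integer(p1 > 0.5), score = as.numeric(p1))
      } else {
        cl <- as.integer(as.character(
          stats::predict(fit$model, data = x, num.threads = 1L)$predictions))
        list(class = cl, score = as.numeric(cl))
      }
    })
}

## ---- scoring and folds ----------------------------------------------------

#' Macro-averaged F1 score for binary labels
#'
#' Mean of the per-class F1 scores; a class with an undefined F1 (no true or
#' predicted members) contributes 0.
#'
#' @param y_true,y_pred Integer 0/1 vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
f1_macro <- function(y_true, y_pred) {
  f1_of <- function(pos) {
    tp <- sum(y_true == pos & y_pred == pos)
    fp <- sum(y_true != pos & y_pred == pos)
    fn <- sum(y_true == pos & y_pred != pos)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  (f1_of(1L) + f1_of(0L)) / 2
}

## Stratified k-fold assignment: per class, shuffle then deal round-robin.
stratified_folds <- function(y, k = 5L, seed = 42L) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (any(vapply(seq_len(k), function(f) length(unique(y[folds != f])), integer(1)) < 2L))
    stop(pcg_error("pcg_single_class_fold", "a CV fold lost one of the classes"))
  folds
}

## Fast wrapped estimators used inside forward selection: fit on a training
## fold, predict classes on a validation fold. Kept deliberately lightweight.
light_fit_predict <- function(estimator, x_tr, y_tr, x_va, seed = 42L) {
  switch(estimator,
    logreg = {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, x_tr), y_tr, family = stats::binomial(),
                       control = list(maxit = 8)))  # enough for a ranking scorer;
                                                    # caps runaway iteration on separable folds
      eta <- cbind(1, x_va) %*% fit$coefficients
      eta[is.na(eta)] <- 0
      as.integer(eta > 0)
    },
    svm_rbf = {
      m <- e1071::svm(x_tr, factor(y_tr, levels = c(0L, 1L)), kernel = "radial",
                      cost = 1, gamma = resolve_gamma("scale", x_tr),
                      scale = FALSE, fitted = FALSE)
      as.integer(as.character(stats::predict(m, x_va)))
    },
    dtree = {
      f <- fit_clf("dtree", list(criterion = "gini", max_depth = 8L, min_leaf = 1L),
                   x_tr, y_tr)
      predict_clf(f, x_va)$class
    },
    rforest = {
      f <- fit_clf("rforest", list(num_trees = 100L, max_depth = 0L, sampling = "sqrt"),
                   x_tr, y_tr, seed = seed)
      predict_clf(f, x_va)$class
    },
    stop(pcg_error("pcg_bad_algorithm", sprintf("unknown estimator '%s'", estimator))))
}
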