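#' The 15-dataset hybrid feature grid
#'
#' Cartesian product of the MFCC dimensionalities (8, 12, 16, 20, 26) with
#' the Daubechies families (db4, db6, db8), MFCC-major; each dataset has
#' `2 * n_mfcc + 30` features.
#'
#' @return Data frame with columns `dataset_id`, `n_mfcc`, `family`,
#'   `total_features`.
#' @export
dataset_grid <- function() {
  n_mfcc <- rep(c(8L, 12L, 16L, 20L, 26L), each = 3L)
  family <- rep(c("db4", "db6", "db8"), times = 5L)
  data.frame(dataset_id = 1:15, n_mfcc = n_mfcc, family = family,
             total_features = 2L * n_mfcc + 30L, stringsAsFactors = FALSE)
}

#' Hybrid MFCC + wavelet feature table
#'
#' For each recording, the `2 * n_mfcc` MFCC summary features followed by
#' the 30 wavelet subband features, plus a binary label column
#' (normal = 0, abnormal = 1). Row order follows the input order.
#'
#' @param recordings List of [pcg_recording()]s, already standardized to the
#'   analysis duration and carrying binarized labels.
#' @param spec One row of [dataset_grid()] (or a list with `n_mfcc` and
#'   `family`).
#' @return Data frame: `record_id`, feature columns, `label` (integer 0/1),
#'   with attribute `"spec"`.
#' @export
build_hybrid_table <- function(recordings, spec) {
  fam <- daubechies_filters(as.integer(sub("db", "", spec$family)))
  rows <- lapply(recordings, function(rec) {
    feats <- tryCatch(
      c(mfcc_features(rec, n_mfcc = spec$n_mfcc), wavelet_features(rec, family = fam)),
      error = function(e) stop(pcg_error(
        "pcg_extraction_failed",
        sprintf("feature extraction failed for record '%s': %s",
                rec$record_id, conditionMessage(e)))))
    feats
  })
  feat <- do.call(rbind, rows)
  labels <- vapply(recordings, function(r) r$label, character(1))
  bad <- !labels %in% c("normal", "abnormal")
  if (any(bad))
    stop(pcg_error("pcg_bad_label",
                   sprintf("non-binarized label for record(s): %s",
                           paste(vapply(recordings[bad], function(r) r$record_id,
                                        character(1)), collapse = ", "))))
  out <- data.frame(record_id = vapply(recordings, function(r) r$record_id, character(1)),
                    feat, label = as.integer(labels == "abnormal"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("record_id", "label"))
}

#' Write a hybrid feature table as CSV with a JSON sidecar
#'
#' The CSV is named `dataset_{id}_{nmfcc}mfcc_{family}.csv` (one row per
#' recording, deterministic column order, label last); the sidecar JSON
#' records the dataset spec and, when given, the z-score parameters used.
#'
#' @param table A [build_hybrid_table()] result (its `"spec"` attribute
#'   supplies the file name).
#' @param dir Output directory.
#' @param scaler Optional [zscore_fit()] parameters to record in the sidecar.
#' @return The CSV path, invisibly.
#' @export
write_feature_table <- function(table, dir, scaler = NULL) {
  spec <- attr(table, "spec")
  if (is.null(spec))
    stop(pcg_error("pcg_bad_table", "table carries no dataset spec attribute"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- sprintf("dataset_%02d_%dmfcc_%s", spec$dataset_id, spec$n_mfcc, spec$family)
  csv <- file.path(dir, paste0(base, ".csv"))
  utils::write.csv(as.data.frame(table), csv, row.names = FALSE)
  side <- list(spec = as.list(spec), n_rows = nrow(table),
               features = feature_columns(table))
  if (!is.null(scaler))
    side$scaler <- list(mu = as.list(scaler$mu), sigma = as.list(scaler$sigma))
  jsonlite::write_json(side, file.path(dir, paste0(base, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(csv)
}

#' Fit z-score standardization parameters on training rows
#'
#' Per-feature mean and population standard deviation, fitted on the
#' training table only. Constant (zero-variance) columns are flagged and
#' later transformed to all-zeros with a warning rather than erroring.
#'
#' @param train Feature table (from [build_hybrid_table()]) or numeric matrix.
#' @return A list of class `zscore_params` with `mu`, `sigma`, `features`.
#' @export
zscore_fit <- function(train) {
  x <- as.matrix(train[feature_columns(train)])
  if (nrow(x) == 0L) stop(pcg_error("pcg_empty_table", "empty training table"))
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(x^2) - mu^2)
  sigma[is.nan(sigma)] <- 0
  if (any(sigma == 0))
    warning(sprintf("constant training column(s) transform to zero: %s",
                    paste(names(sigma)[sigma == 0], collapse = ", ")))
  structure(list(mu = mu, sigma = sigma, features = colnames(x)),
            class = "zscore_params")
}

#' Apply fitted z-score standardization
#'
#' `(x - mu) / sigma` per feature, using training-set parameters only;
#' columns that were constant in training become all-zeros.
#'
#' @param params A [zscore_fit()] result.
#' @param table Feature table with the same feature columns.
#' @return The standardized table.
#' @export
zscore_apply <- function(params, table) {
  stopifnot(inherits(params, "zscore_params"))
  if (!all(params$features %in% names(table)))
    stop(pcg_error("pcg_shape_mismatch", "table lacks fitted feature columns"))
  for (f in params$features) {
    if (params$sigma[[f]] == 0) {
      table[[f]] <- rep(0, nrow(table))
    } else {
      table[[f]] <- (table[[f]] - params$mu[[f]]) / params$sigma[[f]]
    }
  }
  table
}
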