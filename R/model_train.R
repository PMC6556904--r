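## Per-protease SVR training with grid search and 5-fold cross-validation,
## scoring of new windows, and model-bundle (de)serialization.

.MODEL_FORMAT_VERSION <- 1L

#' Train a per-protease cleavage-site SVR model
#'
#' Columns are min-max scaled to \[0, 1\] from the training data only; an
#' RBF-kernel epsilon-SVR is fitted on 0/1 targets; hyperparameters are
#' chosen by grid search maximizing mean cross-validated AUC (shared folds
#' across the grid); the final model is refitted on all training rows at the
#' best grid point. The returned bundle records everything needed to
#' reproduce scores.
#'
#' @param features Feature matrix (samples x features) with manifest column
#'   names.
#' @param labels 0/1 labels (both classes required).
#' @param protease_id Protease identifier stored in the bundle.
#' @param grid Hyperparameter grid (default [default_svr_grid()]).
#' @param folds CV folds for the grid search (default 5).
#' @param seed Seed fixing the fold assignment.
#' @param schemes Character vector of enabled scheme tags (provenance).
#' @param aaindex_version AAindex list version label (provenance; scored
#'   feature vectors must come from the same list).
#' @param knn_ref Optional [knn_reference()] snapshot to store for scanning.
#' @return Object of class `protease_model`.
#' @export
train_model <- function(features, labels, protease_id = "unspecified",
                        grid = default_svr_grid(), folds = 5L, seed = 1L,
                        schemes = NULL, aaindex_version = NULL,
                        knn_ref = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  stopifnot(nrow(features) == length(labels))
  bad <- which(apply(features, 2L, function(x) any(!is.finite(x))))
  if (length(bad) > 0L) {
    stop("non-finite feature value(s) in column(s): ",
         paste(colnames(features)[bad], collapse = ", "))
  }
  fold_id <- make_folds(labels, folds, seed)
  search <- svr_grid_search(features, labels, grid, fold_id)
  sc <- .scale_fit(features)
  fit <- e1071::svm(.scale_apply(features, sc), labels,
                    type = "eps-regression", kernel = "radial",
                    cost = search$best$cost, gamma = search$best$gamma,
                    epsilon = search$best$epsilon, scale = FALSE)
  structure(list(protease_id = protease_id,
                 columns = colnames(features),
                 scaling = sc,
                 params = search$best,
                 model = fit,
                 grid_results = search$results,
                 cv_auc = search$best$cv_auc,
                 schemes = schemes,
                 aaindex_version = aaindex_version,
                 knn_ref = knn_ref,
                 thresholds = NULL,
                 seed = seed,
                 format_version = .MODEL_FORMAT_VERSION),
            class = "protease_model")
}

#' @export
print.protease_model <- function(x, ...) {
  cat("protease cleavage-site model\n",
      "  protease:   ", x$protease_id, "\n",
      "  features:   ", length(x$columns), "\n",
      "  SVR params: C=", x$params$cost, " gamma=", x$params$gamma,
      " epsilon=", x$params$epsilon, "\n",
      "  CV AUC:     ", round(x$cv_auc, 4), "\n", sep = "")
  invisible(x)
}

#' Score feature vectors with a trained model
#'
#' Applies the bundle's stored min-max scaling and SVR, then clips the raw
#' regression outputs to \[0, 1\] so they read as cleavage propensity scores.
#'
#' @param bundle `protease_model` from [train_model()].
#' @param features Feature matrix whose columns cover the bundle's selected
#'   columns (matched by name; extra columns are ignored).
#' @return Numeric vector of scores in \[0, 1\], one per row.
#' @export
predict_scores <- function(bundle, features) {
  stopifnot(inherits(bundle, "protease_model"))
  missing <- setdiff(bundle$columns, colnames(features))
  if (length(missing) > 0L) {
    stop("feature matrix is missing ", length(missing),
         " column(s) required by the model, e.g.: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  x <- features[, bundle$columns, drop = FALSE]
  raw <- as.numeric(stats::predict(bundle$model,
                                   .scale_apply(x, bundle$scaling)))
  pmin(pmax(raw, 0), 1)
}

#' Calibrate specificity thresholds on a set of negative scores
#'
#' Stores, for each target specificity, the score threshold returned by
#' [threshold_at_specificity()] on the supplied training negatives.
#'
#' @param bundle `protease_model`.
#' @param neg_scores Scores of (training) negative windows.
#' @param targets Target specificities (default 0.90, 0.95, 0.99, 1.00).
#' @return The bundle with its `thresholds` table filled in.
#' @export
calibrate_thresholds <- function(bundle, neg_scores,
                                 targets = c(0.90, 0.95, 0.99, 1.00)) {
  stopifnot(inherits(bundle, "protease_model"))
  thr <- vapply(targets, threshold_at_specificity, numeric(1),
                neg_scores = neg_scores)
  bundle$thresholds <- data.frame(specificity = targets, threshold = thr)
  bundle
}

#' Save / load a trained model bundle
#'
#' The on-disk form is version-stamped; loading a bundle written under a
#' different format version, or under a different AAindex list than the one
#' expected, is refused with an explicit error.
#'
#' @param bundle `protease_model`.
#' @param path File path.
#' @param expect_aaindex_version If non-`NULL`, the AAindex list version the
#'   caller's encoding context uses; a mismatching bundle is refused.
#' @return `path` (save) or the restored `protease_model` (load).
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "protease_model"))
  saveRDS(list(format = "procleave-model",
               format_version = .MODEL_FORMAT_VERSION,
               bundle = bundle), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, expect_aaindex_version = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot load model from ", path, ": ", conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, "procleave-model")) {
    stop("not a procleave model file: ", path)
  }
  if (!identical(obj$format_version, .MODEL_FORMAT_VERSION)) {
    stop("model format version mismatch: file has ", obj$format_version,
         ", this package reads ", .MODEL_FORMAT_VERSION)
  }
  bundle <- obj$bundle
  if (!is.null(expect_aaindex_version) &&
      !identical(bundle$aaindex_version, expect_aaindex_version)) {
    stop("AAindex list version mismatch: model was trained with '",
         bundle$aaindex_version, "' but the context provides '",
         expect_aaindex_version, "'")
  }
  bundle
}
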