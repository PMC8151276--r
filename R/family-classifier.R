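#' Cross-validation configuration for classifier training
#'
#' @param folds Number of stratified CV folds (default 5).
#' @param repeats Number of CV repeats (default 10).  Setting either to
#'   0 skips cross-validation entirely (the middle of the tuning grid is
#'   then used as-is).
#' @return A `cv_config` list.
#' @export
cv_config <- function(folds = 5, repeats = 10) {
  if (folds != 0) folds <- check_count(folds, "folds", min = 2)
  if (repeats != 0) repeats <- check_count(repeats, "repeats", min = 1)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats)),
            class = "cv_config")
}

default_mtry_grid <- function(p) {
  g <- unique(pmax(1L, pmin(p, round(sqrt(p) * c(0.5, 1, 2)))))
  sort(g)
}

#' Train the multiclass random-forest GPCR-family classifier
#'
#' Fits a random forest (500 trees by default) relating fingerprint
#' features to GPCR family labels.  The features-per-split parameter
#' ('mtry') is selected by mean accuracy over stratified k-fold
#' cross-validation repeated r times, on a small grid centered on
#' sqrt(p); the winning setting is refit on the full training matrix.
#' Training runs in the bundled scikit-learn backend and is
#' deterministic given `seed`.
#'
#' @param x Numeric feature matrix (training compounds x masked features).
#' @param labels Character/factor vector of family labels, one per row.
#' @param cv A [cv_config()].
#' @param num_trees Trees in the ensemble (default 500).
#' @param mtry_grid Integer vector of candidate features-per-split
#'   values; default is 3 values centered on sqrt(p).
#' @param seed Integer seed.
#' @param feature_mask Optional [fit_nzv_mask()] object stored with the
#'   model for bookkeeping.
#' @param model_path Where to persist the fitted ensemble (joblib file);
#'   defaults to a session temporary file.
#' @return A `family_classifier` object.
#' @export
train_family_classifier <- function(x, labels, cv = cv_config(),
                                    num_trees = 500, mtry_grid = NULL,
                                    seed = 1L, feature_mask = NULL,
                                    model_path = NULL) {
  stopifnot(inherits(cv, "cv_config"))
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) schema_error("row/label length mismatch")
  classes <- sort(unique(labels))
  if (length(classes) < 2) schema_error("need >= 2 classes")
  if (cv$folds > 0) {
    small <- names(which(table(labels) < cv$folds))
    if (length(small)) {
      stop(sprintf("class(es) with fewer members than folds=%d: %s",
                   cv$folds, paste(small, collapse = ", ")), call. = FALSE)
    }
  }
  mtry_grid <- mtry_grid %||% default_mtry_grid(ncol(x))
  model_path <- model_path %||% tempfile("rf_model_", fileext = ".joblib")

  xfile <- tempfile("x_", fileext = ".csv")
  yfile <- tempfile("y_", fileext = ".txt")
  jfile <- tempfile("meta_", fileext = ".json")
  on.exit(unlink(c(xfile, yfile, jfile)), add = TRUE)
  utils::write.table(x, xfile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  writeLines(labels, yfile)
  run_py(py_helper("rf.py"),
         c("train", "--x", shQuote(xfile), "--y", shQuote(yfile),
           "--model", shQuote(model_path), "--json", shQuote(jfile),
           "--trees", num_trees, "--folds", cv$folds,
           "--repeats", cv$repeats,
           "--grid", paste(mtry_grid, collapse = ","),
           "--seed", as.integer(seed)))
  meta <- jsonlite::read_json(jfile, simplifyVector = TRUE)
  structure(list(model_path = model_path,
                 class_labels = meta$classes,
                 feature_labels = colnames(x),
                 feature_mask = feature_mask,
                 cv = cv,
                 tuning = meta$cv,
                 best_mtry = meta$best_mtry,
                 num_trees = num_trees,
                 seed = as.integer(seed)),
            class = "family_classifier")
}

#' @export
print.family_classifier <- function(x, ...) {
  cat(sprintf("<family_classifier> %d classes, %d features, %d trees, mtry=%d (CV %dx%d)\n",
              length(x$class_labels), length(x$feature_labels), x$num_trees,
              x$best_mtry, x$cv$folds, x$cv$repeats))
  invisible(x)
}

check_feature_columns <- function(model, x) {
  if (ncol(x) != length(model$feature_labels)) {
    schema_error(sprintf("matrix has %d columns; model expects %d",
                         ncol(x), length(model$feature_labels)))
  }
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), model$feature_labels)) {
    schema_error("matrix column labels differ from the model's features")
  }
  invisible(x)
}

#' Per-compound family classification probabilities
#'
#' @param model A [train_family_classifier()] fit.
#' @param x Feature matrix with the model's columns.
#' @return Matrix (compounds x classes) of probabilities; rows sum to 1.
#' @export
predict_family_probs <- function(model, x) {
  stopifnot(inherits(model, "family_classifier"))
  check_feature_columns(model, x)
  xfile <- tempfile("x_", fileext = ".csv")
  pfile <- tempfile("p_", fileext = ".csv")
  on.exit(unlink(c(xfile, pfile)), add = TRUE)
  utils::write.table(x, xfile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  run_py(py_helper("rf.py"),
         c("predict", "--model", shQuote(model$model_path),
           "--x", shQuote(xfile), "--out", shQuote(pfile)))
  p <- as.matrix(utils::read.csv(pfile, header = FALSE))
  dimnames(p) <- list(rownames(x), model$class_labels)
  p
}

#' Top-family prediction (argmax of class probabilities)
#'
#' Ties break deterministically to the first family in the model's
#' class-label order.
#'
#' @inheritParams predict_family_probs
#' @return Character vector of predicted family labels.
#' @export
predict_top_family <- function(model, x) {
  p <- predict_family_probs(model, x)
  model$class_labels[max.col(p, ties.method = "first")]
}

one_vs_rest_counts <- function(confusion) {
  total <- sum(confusion)
  k <- nrow(confusion)
  out <- data.frame(family = rownames(confusion),
                    tp = NA_real_, fp = NA_real_, tn = NA_real_,
                    fn = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    fp <- sum(confusion[, i]) - tp
    out$tp[i] <- tp; out$fn[i] <- fn; out$fp[i] <- fp
    out$tn[i] <- total - tp - fn - fp
  }
  out
}

metrics_from_counts <- function(counts) {
  within(counts, {
    accuracy <- 100 * (tp + tn) / (tp + fn + tn + fp)
    sensitivity <- 100 * tp / (tp + fn)
    specificity <- 100 * tn / (tn + fp)
  })
}

#' Per-family classification metrics from prediction lists
#'
#' Builds the K x K confusion matrix from paired true/predicted labels
#' and derives per-family one-vs-rest counts and percent-scale metrics:
#' Accuracy = (TP+TN)/(TP+FN+TN+FP), Sensitivity = TP/(TP+FN),
#' Specificity = TN/(TN+FP).
#'
#' @param true,predicted Label vectors of equal length.
#' @param classes Optional class order (default: sorted union).
#' @return List with `confusion` (rows = true, columns = predicted),
#'   `per_family` (counts and metrics), and `overall_accuracy`
#'   (trace over total, percent).
#' @export
confusion_metrics <- function(true, predicted, classes = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted)) {
    schema_error("true/predicted length mismatch")
  }
  classes <- classes %||% sort(unique(c(true, predicted)))
  confusion <- unclass(table(true = factor(true, levels = classes),
                             predicted = factor(predicted, levels = classes)))
  list(confusion = confusion,
       per_family = metrics_from_counts(one_vs_rest_counts(confusion)),
       overall_accuracy = 100 * sum(diag(confusion)) / sum(confusion))
}

#' Evaluate a classifier on labelled test data
#'
#' Builds the K x K confusion matrix (rows = true family, columns =
#' predicted) and per-family one-vs-rest accuracy, sensitivity and
#' specificity using Accuracy = (TP+TN)/(TP+FN+TN+FP), Sensitivity =
#' TP/(TP+FN), Specificity = TN/(TN+FP), all on the percent scale.
#' Overall accuracy is the confusion-matrix trace over the total.
#'
#' @inheritParams predict_family_probs
#' @param labels True family labels; must all be known to the model.
#' @return A `classifier_eval` object: `confusion`, `per_family`,
#'   `overall_accuracy` (percent), `n`.
#' @export
evaluate_classifier <- function(model, x, labels) {
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), model$class_labels)
  if (length(unknown)) {
    schema_error(sprintf("label(s) outside the model's classes: %s",
                         paste(unknown, collapse = ", ")))
  }
  pred <- predict_top_family(model, x)
  cm <- confusion_metrics(labels, pred, classes = model$class_labels)
  structure(c(cm, list(n = sum(cm$confusion))), class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("<classifier_eval> n=%d, overall accuracy %.1f%%\n",
              x$n, x$overall_accuracy))
  invisible(x)
}

#' Persist / restore a trained classifier
#'
#' A model directory holds the joblib ensemble (`model.joblib`) next to
#' a versioned JSON metadata file (`model.json`: classes, feature
#' labels, mask, CV record, seeds).
#'
#' @param model A `family_classifier`.
#' @param dir Target directory (created if needed).
#' @return `save_family_classifier()`: the directory, invisibly.
#'   `load_family_classifier()`: the restored `family_classifier`.
#' @export
save_family_classifier <- function(model, dir) {
  stopifnot(inherits(model, "family_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  file.copy(model$model_path, file.path(dir, "model.joblib"),
            overwrite = TRUE)
  meta <- model[setdiff(names(model), "model_path")]
  meta$cv <- unclass(meta$cv)
  meta$format_version <- 1L
  meta$feature_mask <- if (!is.null(model$feature_mask)) {
    unclass(model$feature_mask)
  }
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_family_classifier
#' @export
load_family_classifier <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  if (!identical(as.integer(meta$format_version), 1L)) {
    schema_error("unsupported model format version")
  }
  mask <- if (!is.null(meta$feature_mask)) {
    structure(meta$feature_mask, class = "feature_mask")
  }
  structure(list(model_path = file.path(dir, "model.joblib"),
                 class_labels = meta$class_labels,
                 feature_labels = meta$feature_labels,
                 feature_mask = mask,
                 cv = structure(meta$cv, class = "cv_config"),
                 tuning = meta$tuning,
                 best_mtry = meta$best_mtry,
                 num_trees = meta$num_trees,
                 seed = meta$seed),
            class = "family_classifier")
}

#' Randomized-label control
#'
#' Permutes the family labels uniformly, splits the data 70/30
#' stratified by the permuted labels, retrains the classifier on the
#' training part, and reports held-out top-1 accuracy.  With K balanced
#' classes the expected accuracy is 1/K, confirming the trained model's
#' accuracy is label-driven rather than structural.
#'
#' @param x Feature matrix.
#' @param labels True labels (permuted internally).
#' @param seed Integer seed controlling the permutation, split and fit.
#' @param cv CV configuration for the control fit; default skips tuning
#'   (`cv_config(0, 0)`), which does not change the expected result.
#' @param ... Passed to [train_family_classifier()].
#' @return List with `accuracy` (fraction in [0,1]), `n_test`, `k`.
#' @export
randomized_label_control <- function(x, labels, seed = 1L,
                                     cv = cv_config(0, 0), ...) {
  labels <- as.character(labels)
  perm <- with_seed(seed, sample(labels))
  df <- data.frame(idx = seq_along(perm), family = perm,
                   stringsAsFactors = FALSE)
  split <- stratified_split(df, train_fraction = 0.70, seed = seed + 1L)
  tr <- split$training; te <- split$test
  model <- train_family_classifier(x[tr$idx, , drop = FALSE], tr$family,
                                   cv = cv, seed = seed, ...)
  pred <- predict_top_family(model, x[te$idx, , drop = FALSE])
  list(accuracy = mean(pred == te$family),
       n_test = nrow(te),
       k = length(unique(labels)))
}
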