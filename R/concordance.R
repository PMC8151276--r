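#' Consolidate screen results into a scaffold x family confirmation matrix
#'
#' Screening results for all tracer candidates of a scaffold, at every
#' tested concentration, are grouped by GPCR family: a (scaffold,
#' family) cell is confirmed positive iff at least one member construct
#' shows a fold response at or above the threshold for any candidate
#' tracer at any concentration.  Constructs absent from the family map
#' are excluded with a warning.
#'
#' @param results Data.frame with columns `scaffold`, `construct` and
#'   `fold_response` (e.g. a [screen_summary()] augmented with the
#'   scaffold each tracer derives from).
#' @param family_map Data.frame with columns `construct`, `family`.
#' @param fold_threshold Positivity threshold (default 1.5).
#' @param families Optional column order; defaults to the sorted mapped
#'   families.
#' @param scaffolds Optional row order.
#' @return Binary scaffold x family matrix.
#' @export
consolidate_screen <- function(results, family_map, fold_threshold = 1.5,
                               families = NULL, scaffolds = NULL) {
  require_columns(results, c("scaffold", "construct", "fold_response"),
                  "screen results")
  require_columns(family_map, c("construct", "family"), "family map")
  fam <- family_map$family[match(results$construct, family_map$construct)]
  if (anyNA(fam)) {
    warning(sprintf("excluding %d result row(s) for unmapped construct(s): %s",
                    sum(is.na(fam)),
                    paste(unique(results$construct[is.na(fam)]), collapse = ", ")),
            call. = FALSE)
    results <- results[!is.na(fam), , drop = FALSE]
    fam <- fam[!is.na(fam)]
  }
  scaffolds <- scaffolds %||% sort(unique(results$scaffold))
  families <- families %||% sort(unique(family_map$family))
  m <- matrix(0L, length(scaffolds), length(families),
              dimnames = list(scaffolds, families))
  pos <- results$fold_response >= fold_threshold
  if (any(pos)) {
    hits <- unique(data.frame(s = results$scaffold[pos], f = fam[pos]))
    m[cbind(match(hits$s, scaffolds), match(hits$f, families))] <- 1L
  }
  m
}

#' Overlap analysis between predictions and screen confirmations
#'
#' Tallies the cellwise 2x2 agreement between a binary prediction
#' matrix and a binary confirmation matrix and derives percent-scale
#' accuracy, sensitivity and specificity via Accuracy =
#' (TP+TN)/(TP+FN+TN+FP), Sensitivity = TP/(TP+FN), Specificity =
#' TN/(TN+FP), plus the positive-confirmation rate TP/(TP+FP).
#' "Positive" counts are anchored on predictions: TP = predicted and
#' confirmed, FN = confirmed but not predicted.
#'
#' @param predictions,confirmations Binary matrices of identical shape
#'   and dimnames.
#' @return A `concordance_table` list: `tp`, `fp`, `fn`, `tn`,
#'   `accuracy`, `sensitivity`, `specificity`,
#'   `positive_confirmation_rate`, `n_cells`.
#' @export
overlap_concordance <- function(predictions, confirmations) {
  if (!identical(dim(predictions), dim(confirmations))) {
    schema_error("prediction and confirmation matrices differ in shape")
  }
  if (!is.null(dimnames(predictions)) && !is.null(dimnames(confirmations)) &&
      !identical(dimnames(predictions), dimnames(confirmations))) {
    schema_error("prediction and confirmation matrices differ in labels")
  }
  p <- predictions != 0
  c_ <- confirmations != 0
  tp <- sum(p & c_); fp <- sum(p & !c_)
  fn <- sum(!p & c_); tn <- sum(!p & !c_)
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    positive_confirmation_rate = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    n_cells = length(p)),
    class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("<concordance_table> %d cells | TP %d FP %d FN %d TN %d | acc %.1f%% sens %.1f%% spec %.1f%% ppv %.1f%%\n",
              x$n_cells, x$tp, x$fp, x$fn, x$tn, x$accuracy, x$sensitivity,
              x$specificity, x$positive_confirmation_rate))
  invisible(x)
}

#' Sweep the probability threshold against screen confirmations
#'
#' Recomputes the concordance table for each candidate probability
#' threshold and reports the threshold maximizing balanced accuracy
#' (the mean of sensitivity and specificity), an explicit stand-in for
#' "best balance between accuracy and false predictions".
#'
#' @param profiles Percent-scale probability matrix (scaffolds x
#'   families), e.g. [probability_profiles()].
#' @param confirmations Binary confirmation matrix with matching
#'   dimnames.
#' @param thresholds Numeric vector of percent thresholds (non-empty).
#' @return List with `metrics` (one row per threshold), `tables`
#'   (concordance tables), and `best_threshold`.
#' @export
threshold_sweep <- function(profiles, confirmations, thresholds) {
  if (length(thresholds) == 0) config_error("threshold list is empty")
  families <- colnames(confirmations)
  tables <- lapply(thresholds, function(t) {
    pred <- profile_matrix(profiles, families, threshold = t)
    rownames(pred) <- rownames(profiles)
    overlap_concordance(pred[rownames(confirmations), , drop = FALSE],
                        confirmations)
  })
  names(tables) <- as.character(thresholds)
  metrics <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tt <- tables[[i]]
    data.frame(threshold = thresholds[i], tp = tt$tp, fp = tt$fp,
               fn = tt$fn, tn = tt$tn, accuracy = tt$accuracy,
               sensitivity = tt$sensitivity, specificity = tt$specificity,
               balanced_accuracy = mean(c(tt$sensitivity, tt$specificity)))
  }))
  best <- thresholds[which.max(metrics$balanced_accuracy)]
  list(metrics = metrics, tables = tables, best_threshold = best)
}
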