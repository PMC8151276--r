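#' Ingestion filter for raw GPCR-ligand interaction tables
#'
#' Keeps records that (i) are annotated for the human receptor, (ii)
#' carry a non-missing compound identifier, and (iii) have a parseable
#' SMILES.  Parse failures are dropped with a logged count.  A
#' `canonical_smiles` column is added so downstream steps can reuse the
#' canonical structure without re-parsing.
#'
#' @param raw Data.frame with columns `compound_id`, `smiles`,
#'   `receptor`, `species`, `family`.
#' @param species_keep Species tag to retain (default `"human"`,
#'   case-insensitive).
#' @return The filtered data.frame.
#' @export
filter_records <- function(raw, species_keep = "human") {
  require_columns(raw, c("compound_id", "smiles", "receptor", "species",
                         "family"), "interaction table")
  keep <- tolower(trimws(raw$species)) == tolower(species_keep) &
    !is.na(raw$compound_id) & nzchar(trimws(as.character(raw$compound_id))) &
    !is.na(raw$smiles) & nzchar(trimws(raw$smiles))
  out <- raw[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    rownames(out) <- NULL
    out$canonical_smiles <- character(0)
    return(out)
  }
  canon <- canonical_smiles(out$smiles)
  n_bad <- sum(is.na(canon))
  if (n_bad > 0) {
    message(sprintf("filter_records: dropped %d record(s) with unparseable SMILES",
                    n_bad))
  }
  out$canonical_smiles <- canon
  out <- out[!is.na(canon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse records to unique compound-family combinations
#'
#' The deduplication key is the canonical structure, not the raw SMILES
#' spelling, so two spellings of one molecule collapse; a compound
#' annotated against k families keeps k records (one per family).
#' First occurrence wins.
#'
#' @param records Data.frame with `smiles` and `family` columns (a
#'   `canonical_smiles` column from [filter_records()] is reused when
#'   present).
#' @return Deduplicated data.frame.
#' @export
deduplicate <- function(records) {
  require_columns(records, c("smiles", "family"), "interaction table")
  if (nrow(records) == 0) return(records)
  canon <- records$canonical_smiles
  if (is.null(canon)) {
    canon <- canonical_smiles(records$smiles)
    records$canonical_smiles <- canon
  }
  key <- paste(canon, records$family, sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop families with too few unique compounds
#'
#' @param records Deduplicated interaction table.
#' @param min_compounds Minimum unique compounds a family must have
#'   (default 700).
#' @return Records of the retained families only.
#' @export
family_threshold_filter <- function(records, min_compounds = 700) {
  require_columns(records, c("family"), "interaction table")
  counts <- table(records$family)
  keep_fams <- names(counts)[counts >= min_compounds]
  if (length(keep_fams) == 0) {
    stop(sprintf("no family reaches the %d unique-compound threshold",
                 min_compounds), call. = FALSE)
  }
  out <- records[records$family %in% keep_fams, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balanced random selection of records per family
#'
#' Draws exactly `n_per_family` records per family, uniformly without
#' replacement, producing an exactly class-balanced dataset.
#'
#' @param records Deduplicated, threshold-filtered table.
#' @param n_per_family Records to keep per family (default 530).
#' @param seed Integer seed; the selection is deterministic given it.
#' @return Balanced data.frame.
#' @export
balanced_select <- function(records, n_per_family = 530, seed = 1L) {
  require_columns(records, c("family"), "interaction table")
  n_per_family <- check_count(n_per_family, "n_per_family")
  counts <- table(records$family)
  short <- names(counts)[counts < n_per_family]
  if (length(short)) {
    stop(sprintf("family below n_per_family=%d: %s", n_per_family,
                 paste(short, collapse = ", ")), call. = FALSE)
  }
  with_seed(seed, {
    idx <- unlist(lapply(split(seq_len(nrow(records)), records$family),
                         function(i) i[sample.int(length(i), n_per_family)]),
                  use.names = FALSE)
  })
  out <- records[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Splits each family independently: `floor(train_fraction * n)` records
#' to training, the remainder to test, so a balanced 530-per-family
#' input yields 371 training and 159 test records per family.
#'
#' @param selected Balanced interaction table.
#' @param train_fraction Fraction of each family used for training
#'   (default 0.70; must lie in (0, 1]).
#' @param seed Integer seed.
#' @return A `dataset_split` object with `training`, `test` and
#'   `per_family_counts` components.
#' @export
stratified_split <- function(selected, train_fraction = 0.70, seed = 1L) {
  require_columns(selected, c("family"), "interaction table")
  if (!is.numeric(train_fraction) || length(train_fraction) != 1 ||
      train_fraction <= 0 || train_fraction > 1) {
    stop("train_fraction must lie in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    groups <- split(seq_len(nrow(selected)), selected$family)
    train_idx <- unlist(lapply(groups, function(i) {
      n_train <- floor(train_fraction * length(i))
      i[sample.int(length(i), n_train)]
    }), use.names = FALSE)
  })
  is_train <- seq_len(nrow(selected)) %in% train_idx
  training <- selected[is_train, , drop = FALSE]
  test <- selected[!is_train, , drop = FALSE]
  rownames(training) <- rownames(test) <- NULL
  fams <- sort(unique(selected$family))
  per_family_counts <- data.frame(
    family = fams,
    n_train = as.integer(table(factor(training$family, levels = fams))),
    n_test = as.integer(table(factor(test$family, levels = fams))),
    stringsAsFactors = FALSE)
  structure(list(training = training, test = test,
                 per_family_counts = per_family_counts,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d training / %d test records across %d families (fraction %.2f)\n",
              nrow(x$training), nrow(x$test), nrow(x$per_family_counts),
              x$train_fraction))
  invisible(x)
}

#' Run the full dataset-construction pipeline
#'
#' Convenience wrapper: ingestion filter, compound-family deduplication,
#' family-size threshold, balanced selection, stratified split.
#'
#' @inheritParams filter_records
#' @inheritParams family_threshold_filter
#' @inheritParams balanced_select
#' @inheritParams stratified_split
#' @return A `dataset_split`.
#' @export
build_dataset <- function(raw, min_compounds = 700, n_per_family = 530,
                          train_fraction = 0.70, seed = 1L) {
  filtered <- filter_records(raw)
  deduped <- deduplicate(filtered)
  thresholded <- family_threshold_filter(deduped, min_compounds)
  selected <- balanced_select(thresholded, n_per_family, seed = seed)
  stratified_split(selected, train_fraction, seed = seed)
}
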