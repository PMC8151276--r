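#' Layout of the 758-position concatenated fingerprint
#'
#' Molecules are encoded as a single numeric vector of 758 positions:
#' a 167-position MACCS structural-key block (position 1 is the reserved
#' key of the public MACCS indexing convention and is always 0), a
#' 79-position block of E-State atom-type counts, and a 512-slot binary
#' functional-group substructure block defined by the SMARTS dialect
#' shipped in `extdata/fgfp_smarts_synthetic.tsv`.
#'
#' @return `fp_length()`: total vector length (758).
#'   `fp_blocks()`: named list of index ranges per block.
#'   `fp_labels()`: the 758 column labels.
#' @export
fp_length <- function() 758L

#' @rdname fp_length
#' @export
fp_blocks <- function() {
  list(maccs = 1:167, estate = 168:246, fg = 247:758)
}

# E-State atom-type order is frozen to the standard 79-type scheme.
ESTATE_TYPES <- c(
  "sLi", "ssBe", "ssssBe", "ssBH", "sssB", "ssssB", "sCH3", "dCH2",
  "ssCH2", "tCH", "dsCH", "aaCH", "sssCH", "ddC", "tsC", "dssC", "aasC",
  "aaaC", "ssssC", "sNH3", "sNH2", "ssNH2", "dNH", "ssNH", "aaNH", "tN",
  "sssNH", "dsN", "aaN", "sssN", "ddsN", "aasN", "ssssN", "sOH", "dO",
  "ssO", "aaO", "sF", "sSiH3", "ssSiH2", "sssSiH", "ssssSi", "sPH2",
  "ssPH", "sssP", "dsssP", "sssssP", "sSH", "dS", "ssS", "aaS", "dssS",
  "ddssS", "sCl", "sGeH3", "ssGeH2", "sssGeH", "ssssGe", "sAsH2",
  "ssAsH", "sssAs", "sssdAs", "sssssAs", "sSeH", "dSe", "ssSe", "aaSe",
  "dssSe", "ddssSe", "sBr", "sSnH3", "ssSnH2", "sssSnH", "ssssSn", "sI",
  "sPbH3", "ssPbH2", "sssPbH", "ssssPb")

#' @rdname fp_length
#' @export
fp_labels <- function() {
  c(sprintf("MACCS%03d", 1:167),
    paste0("ES_", ESTATE_TYPES),
    sprintf("FG%03d", 1:512))
}

fg_pattern_file <- function() {
  system.file("extdata", "fgfp_smarts_synthetic.tsv",
              package = "gpcrtracer", mustWork = TRUE)
}

run_fingerprint_backend <- function(smiles, canon_only = FALSE) {
  fin <- tempfile("smiles_", fileext = ".smi")
  fout <- tempfile("fp_", fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(smiles, fin)
  args <- c("--smiles", shQuote(fin), "--out", shQuote(fout))
  if (canon_only) {
    args <- c(args, "--canon-only")
  } else {
    args <- c(args, "--patterns", shQuote(fg_pattern_file()))
  }
  run_py(py_helper("fingerprints.py"), args)
  utils::read.csv(fout, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = c("integer", "character",
                                 rep("numeric", if (canon_only) 0 else 758)))
}

#' Canonicalize SMILES strings
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES, `NA` where a string
#'   failed to parse.
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  res <- run_fingerprint_backend(as.character(smiles), canon_only = TRUE)
  out <- res[[2]]
  out[res[[1]] == 0] <- NA_character_
  out
}

#' Compute concatenated fingerprints for a set of molecules
#'
#' @param smiles Character vector of SMILES; all must parse.
#' @param ids Optional row names (defaults to the input SMILES).
#' @return Numeric matrix, one row per molecule, 758 labelled columns;
#'   the canonical SMILES are attached as attribute `canonical`.
#' @export
fingerprint_matrix <- function(smiles, ids = NULL) {
  if (length(smiles) == 0) schema_error("no SMILES supplied")
  res <- run_fingerprint_backend(as.character(smiles))
  bad <- which(res[[1]] == 0)
  if (length(bad)) {
    stop(errorCondition(
      sprintf("unparseable SMILES: %s",
              paste(utils::head(smiles[bad], 5), collapse = ", ")),
      class = c("gpcrtracer_encoding_error", "error")))
  }
  m <- as.matrix(res[, -(1:2), drop = FALSE])
  dimnames(m) <- list(ids %||% as.character(smiles), fp_labels())
  attr(m, "canonical") <- res[[2]]
  m
}

#' Compute the 758-position fingerprint of a single molecule
#'
#' @param smiles A single SMILES string.
#' @return Named numeric vector of length 758.
#' @export
compute_fingerprint <- function(smiles) {
  stopifnot(length(smiles) == 1)
  fingerprint_matrix(smiles)[1, ]
}

#' Fit a near-zero-variance feature mask on a training matrix
#'
#' A column is removed iff (a) it takes a single unique value, or
#' (b) its frequency ratio (count of the most common value over the
#' count of the second most common) exceeds `freq_cut` AND its percent
#' of unique values (100 * distinct / rows) is below `unique_cut`.
#' The mask must be fit on training rows only and then applied
#' unchanged to any test matrix.
#'
#' @param training_matrix Numeric matrix (training compounds x features).
#' @param freq_cut Frequency-ratio cutoff (default 95/5 = 19).
#' @param unique_cut Percent-unique cutoff (default 10).
#' @return A `feature_mask` object with the retained column indices.
#' @export
fit_nzv_mask <- function(training_matrix, freq_cut = 95 / 5, unique_cut = 10) {
  if (is.null(dim(training_matrix)) || nrow(training_matrix) == 0) {
    schema_error("training matrix is empty")
  }
  n <- nrow(training_matrix)
  drop <- vapply(seq_len(ncol(training_matrix)), function(j) {
    tab <- sort(table(training_matrix[, j]), decreasing = TRUE)
    if (length(tab) == 1) return(TRUE)
    freq_ratio <- as.numeric(tab[1]) / as.numeric(tab[2])
    pct_unique <- 100 * length(tab) / n
    freq_ratio > freq_cut && pct_unique < unique_cut
  }, logical(1))
  retained <- which(!drop)
  if (length(retained) == 0) {
    schema_error("near-zero-variance filter removed every feature")
  }
  structure(list(retained = retained,
                 labels = colnames(training_matrix)[retained],
                 n_input = ncol(training_matrix),
                 freq_cut = freq_cut, unique_cut = unique_cut),
            class = "feature_mask")
}

#' Apply a fitted feature mask to a fingerprint matrix
#'
#' @param matrix Numeric matrix with the same columns the mask was fit on.
#' @param mask A [fit_nzv_mask()] result.
#' @return The column-subset matrix, in mask order.
#' @export
apply_mask <- function(matrix, mask) {
  stopifnot(inherits(mask, "feature_mask"))
  if (ncol(matrix) != mask$n_input) {
    schema_error(sprintf("matrix has %d columns but the mask was fit on %d",
                         ncol(matrix), mask$n_input))
  }
  matrix[, mask$retained, drop = FALSE]
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %d / %d features retained (freq_cut=%.3g, unique_cut=%.3g)\n",
              length(x$retained), x$n_input, x$freq_cut, x$unique_cut))
  invisible(x)
}

#' Pairwise Tanimoto (Jaccard) similarity of binary fingerprints
#'
#' @param m Binary matrix, rows = molecules.
#' @return Symmetric similarity matrix; pairs of all-zero rows get 0.
#' @export
tanimoto_matrix <- function(m) {
  m <- (m != 0) * 1
  inter <- tcrossprod(m)
  rs <- rowSums(m)
  uni <- outer(rs, rs, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  diag(sim) <- 1
  sim
}
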