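#' Configuration for the chemical-space UMAP embedding
#'
#' @param n_neighbors Size of the local neighbourhood (default 50, the
#'   setting found to balance spread against family clustering).
#' @param n_components Output dimensions (2 for visualization).
#' @param min_dist UMAP minimum distance (default 0.1, the library
#'   default; the choice is documented, not prescribed).
#' @param seed Integer seed; embeddings are deterministic given it.
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(n_neighbors = 50, n_components = 2,
                             min_dist = 0.1, seed = 1L) {
  n_neighbors <- check_count(n_neighbors, "n_neighbors", min = 2)
  n_components <- check_count(n_components, "n_components", min = 1)
  structure(list(n_neighbors = n_neighbors, n_components = n_components,
                 min_dist = min_dist, seed = as.integer(seed)),
            class = "embedding_config")
}

#' Embed MACCS fingerprints into two dimensions with UMAP
#'
#' Consumes the binary MACCS block only, with Jaccard (Tanimoto)
#' distance -- the natural metric for binary structural keys.  The
#' pairwise distance matrix is computed in R and handed to
#' `uwot::umap()`, single-threaded for reproducibility.
#'
#' @param maccs_matrix Binary matrix (compounds x MACCS keys), e.g. the
#'   `maccs` block of a [fingerprint_matrix()].
#' @param config An [embedding_config()].
#' @return Numeric n x 2 (or n x `n_components`) coordinate matrix.
#' @export
embed_chemspace <- function(maccs_matrix, config = embedding_config()) {
  stopifnot(inherits(config, "embedding_config"))
  if (nrow(maccs_matrix) < config$n_neighbors) {
    schema_error(sprintf("need >= n_neighbors=%d rows, got %d",
                         config$n_neighbors, nrow(maccs_matrix)))
  }
  d <- stats::as.dist(1 - tanimoto_matrix(maccs_matrix))
  coords <- uwot::umap(d,
                       n_neighbors = config$n_neighbors,
                       n_components = config$n_components,
                       min_dist = config$min_dist,
                       seed = config$seed,
                       n_threads = 1, n_sgd_threads = 1,
                       batch = TRUE)
  rownames(coords) <- rownames(maccs_matrix)
  colnames(coords) <- paste0("umap", seq_len(ncol(coords)))
  coords
}

#' Explore a range of UMAP neighbourhood sizes
#'
#' Produces one embedding per `n_neighbors` setting under a shared seed,
#' with the mean silhouette of the supplied labels reported per setting
#' for model selection.
#'
#' @inheritParams embed_chemspace
#' @param neighbor_values Integer vector of neighbourhood sizes.
#' @param seed Shared seed.
#' @param labels Optional family labels for silhouette scoring.
#' @return Named list with `embeddings` (list of coordinate matrices)
#'   and `silhouette` (named numeric, `NA` without labels).
#' @export
neighbor_sweep <- function(maccs_matrix, neighbor_values, seed = 1L,
                           labels = NULL) {
  if (length(neighbor_values) == 0) {
    config_error("neighbor_values must be non-empty")
  }
  embeddings <- lapply(neighbor_values, function(k) {
    embed_chemspace(maccs_matrix,
                    embedding_config(n_neighbors = k, seed = seed))
  })
  names(embeddings) <- as.character(neighbor_values)
  sil <- vapply(embeddings, function(e) {
    if (is.null(labels)) NA_real_ else silhouette_score(e, labels)
  }, numeric(1))
  list(embeddings = embeddings, silhouette = sil)
}

#' Mean silhouette width of labelled points in a coordinate space
#'
#' @param coords Numeric coordinate matrix (e.g. a UMAP embedding).
#' @param labels Grouping labels, one per row.
#' @return Mean silhouette width in [-1, 1].
#' @export
silhouette_score <- function(coords, labels) {
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2) schema_error("need >= 2 label groups")
  sil <- cluster::silhouette(cl, stats::dist(coords))
  mean(sil[, "sil_width"])
}
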