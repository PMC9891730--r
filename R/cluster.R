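#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Builds a k-nearest-neighbor graph on the selected PC scores, converts it
#' to a shared-nearest-neighbor (SNN) graph whose edge weights are the
#' Jaccard overlap of the two cells' neighbor sets (each set includes the
#' cell itself), prunes edges with weight below `prune`, and partitions the
#' graph with Louvain modularity optimization at the given resolution.
#' Cluster ids are relabelled 0..K-1 by decreasing size.
#'
#' @param pca a `fru_pca` from [jackstraw_select_pcs()] (its `n_selected`
#'   PCs are used), or a plain cells x PCs score matrix.
#' @param k neighbors for the kNN graph (reduced with a warning when there
#'   are fewer cells).
#' @param resolution Louvain resolution parameter (> 0).
#' @param seed integer seed for the (randomized) community detection.
#' @param prune minimum Jaccard weight kept (default 1/15).
#' @param n_pcs override for the number of PCs to use.
#' @return A list of class `fru_clusters`: `labels` (named integer vector,
#'   0-based), `k`, `resolution`, `seed`, `n_pcs`.
#' @export
cluster_snn <- function(pca, k = 20, resolution = 0.8, seed = 1,
                        prune = 1 / 15, n_pcs = NULL) {
  assert_scalar_num(resolution, "resolution", lower = 0, strict_lower = TRUE)
  assert_scalar_num(seed, "seed", integer = TRUE)
  scores <- score_matrix(pca, n_pcs)
  n <- nrow(scores)
  if (n < 2) stop_field("pca", "need at least 2 cells to cluster")
  if (k >= n) {
    warning(sprintf("k = %d >= %d cells; reducing to %d", k, n, n - 1L))
    k <- n - 1L
  }
  nn <- RANN::nn2(scores, k = k + 1L)$nn.idx   # includes self
  adj <- snn_jaccard(nn, prune)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- relabel_clusters(igraph::membership(comm))
  names(labels) <- rownames(scores)
  structure(list(labels = labels, k = k, resolution = resolution,
                 seed = seed, n_pcs = ncol(scores)),
            class = "fru_clusters")
}

# Jaccard-weighted SNN adjacency from a kNN index matrix (rows = cells,
# columns = neighbor indices, self included)
snn_jaccard <- function(nn, prune) {
  n <- nrow(nn)
  k <- ncol(nn)
  # sparse cell x cell membership, then shared-neighbor counts by crossprod
  memb <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                               x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(memb)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)      # |A n B| / (|A| + |B| - |A n B|)
  jac@x[jac@x < prune] <- 0
  Matrix::drop0(jac)
}

score_matrix <- function(pca, n_pcs = NULL) {
  if (inherits(pca, "fru_pca")) {
    use <- n_pcs %||% pca$n_selected
    if (use < 1)
      stop_field("pca", "0 PCs selected; re-run jackstraw with min_pcs >= 1")
    pca$scores[, seq_len(min(use, ncol(pca$scores))), drop = FALSE]
  } else as.matrix(pca)
}

#' Two-dimensional UMAP embedding of the PC scores
#'
#' Thin wrapper over [uwot::umap()] (single-threaded so a fixed seed gives
#' identical coordinates).
#'
#' @inheritParams cluster_snn
#' @param n_neighbors,min_dist UMAP parameters.
#' @return A cells x 2 matrix of coordinates.
#' @export
umap_embed <- function(pca, seed = 1, n_neighbors = 30, min_dist = 0.3,
                       n_pcs = NULL) {
  scores <- score_matrix(pca, n_pcs)
  n_neighbors <- min(n_neighbors, nrow(scores) - 1L)
  set.seed(seed)
  emb <- uwot::umap(scores, n_neighbors = n_neighbors, min_dist = min_dist,
                    n_threads = 1, n_sgd_threads = 0, batch = FALSE)
  rownames(emb) <- rownames(scores)
  colnames(emb) <- c("UMAP1", "UMAP2")
  emb
}
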