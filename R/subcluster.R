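#' Specification of a targeted subclustering analysis
#'
#' @param source_clusters cluster ids whose cells seed the subanalysis.
#' @param gene_predicates named numeric vector `c(gene = min_umis, ...)`;
#'   a cell is kept when every listed gene has strictly more than `min_umis`
#'   UMIs... i.e. `dsx = 0` keeps cells with dsx UMIs > 0.  Empty = no
#'   predicate.
#' @param n_pcs fixed number of PCs, or `"jackstraw"` to re-select on the
#'   subset.
#' @param resolution Louvain resolution for the subanalysis.
#' @param n_hvg variable genes re-selected within the subset.
#' @param seed integer seed.
#' @return A list of class `subcluster_spec`.
#' @export
subcluster_spec <- function(source_clusters, gene_predicates = numeric(),
                            n_pcs = "jackstraw", resolution = 0.5,
                            n_hvg = 2000, seed = 1) {
  assert_scalar_num(resolution, "resolution", lower = 0, strict_lower = TRUE)
  if (!identical(n_pcs, "jackstraw"))
    assert_scalar_num(n_pcs, "n_pcs", lower = 1, integer = TRUE)
  if (length(gene_predicates) && is.null(names(gene_predicates)))
    stop_field("gene_predicates", "must be a named vector (gene = min_umis)")
  structure(list(source_clusters = source_clusters,
                 gene_predicates = gene_predicates, n_pcs = n_pcs,
                 resolution = resolution, n_hvg = n_hvg, seed = seed),
            class = "subcluster_spec")
}

#' The three canonical subclustering configurations
#'
#' Returns the named configurations used for the doublesex-expressing
#' male-biased clusters (cells kept only with dsx UMIs > 0; 27 PCs,
#' resolution 0.5), the high-confidence mushroom body Kenyon cell clusters
#' (21 PCs, resolution 0.5) and the circadian clusters (2 PCs, resolution
#' 2.5).  Source cluster ids must be supplied by the caller because they are
#' properties of the particular analysis (the defaults for `dsx` are the
#' atlas ids 21, 47 and 68).
#'
#' @param dsx_clusters,kc_clusters,circadian_clusters cluster ids feeding
#'   each configuration.
#' @return Named list of [subcluster_spec] objects (`dsx`, `kc`,
#'   `circadian`).
#' @export
builtin_specs <- function(dsx_clusters = c(21, 47, 68),
                          kc_clusters = integer(),
                          circadian_clusters = integer()) {
  list(
    dsx = subcluster_spec(dsx_clusters, gene_predicates = c(dsx = 0),
                          n_pcs = 27, resolution = 0.5),
    kc = subcluster_spec(kc_clusters, n_pcs = 21, resolution = 0.5),
    circadian = subcluster_spec(circadian_clusters, n_pcs = 2,
                                resolution = 2.5))
}

#' Subset cells and re-run the clustering workflow
#'
#' Cells from the source clusters that satisfy every gene predicate are
#' retained; the parent's normalization is inherited; variable genes and PCA
#' are recomputed on the subset; the PC count is re-selected by jackstraw
#' unless fixed in the spec; the subset is clustered and its markers and
#' per-subcluster sex composition recomputed.
#'
#' @param cm a [fru_counts] (the parent analysis' cells).
#' @param nm the parent's log-normalized matrix.
#' @param labels per-cell cluster labels of the parent analysis.
#' @param spec a [subcluster_spec].
#' @param min_cells minimum subset size (default 10).
#' @param max_pcs cap on PCs computed when jackstraw re-selects.
#' @return A list: `cm` (the subset), `labels` (`fru_clusters`), `pca`,
#'   `markers`, `sex_counts`, `spec`.
#' @export
subset_and_recluster <- function(cm, nm, labels, spec, min_cells = 10,
                                 max_pcs = 20) {
  stopifnot(inherits(spec, "subcluster_spec"))
  labels <- label_vector(labels, cm)
  keep <- labels %in% spec$source_clusters
  for (g in names(spec$gene_predicates)) {
    if (!g %in% cm$gene_ids)
      stop_field("gene_predicates", sprintf("gene '%s' not in matrix", g))
    ok <- cm$counts[g, ] > spec$gene_predicates[[g]]
    keep <- keep & as.logical(ok)
    if (!any(keep))
      stop_field("gene_predicates",
                 sprintf("no cells left after predicate on '%s'", g))
  }
  if (sum(keep) < min_cells)
    stop_field("spec", sprintf("subset has %d cells (< %d)", sum(keep),
                               min_cells))
  sub_cm <- subset_cells(cm, keep)
  sub_nm <- nm[, cm$barcodes[keep], drop = FALSE]
  n_hvg <- min(spec$n_hvg, nrow(sub_cm$counts))
  hvgs <- suppressWarnings(select_hvgs(sub_cm, n = n_hvg))
  if (identical(spec$n_pcs, "jackstraw")) {
    cap <- min(max_pcs, min(dim(sub_nm)) - 1L)
    pca <- suppressWarnings(
      jackstraw_select_pcs(sub_nm, hvgs, max_pcs = cap, seed = spec$seed,
                           min_pcs = 2))
    n_use <- pca$n_selected
    scores <- pca
  } else {
    x <- scale_for_pca(sub_nm, hvgs)
    n_use <- min(spec$n_pcs, min(dim(x)) - 1L)
    pca <- pca_scores(x, n_use)
    scores <- pca$scores
  }
  sub_labels <- cluster_snn(scores, resolution = spec$resolution,
                            seed = spec$seed, n_pcs = n_use)
  markers <- if (length(unique(sub_labels$labels)) >= 2)
    find_markers(sub_cm, sub_nm, sub_labels) else NULL
  list(cm = sub_cm, labels = sub_labels, pca = pca, markers = markers,
       sex_counts = cluster_sex_counts(sub_labels$labels, sub_cm),
       spec = spec)
}
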