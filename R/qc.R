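#' Cell-filtering thresholds
#'
#' Boundary semantics are strict inequalities throughout: a cell is removed
#' only if it is strictly beyond a threshold (mito fraction > `max_mito`,
#' detected genes < `min_genes` or > `max_genes`, UMIs > `max_umis`), so
#' cells sitting exactly on a boundary are kept.  Defaults are the common
#' droplet scRNA-seq cutoffs for fly neurons: >5% mitochondrial UMIs
#' (stressed/dying cells), <200 detected genes (empty droplets),
#' >4000 genes and/or >20,000 UMIs (potential multiplets).
#'
#' @param max_mito maximum mitochondrial UMI fraction (default 0.05).
#' @param min_genes minimum detected genes (default 200).
#' @param max_genes maximum detected genes (default 4000).
#' @param max_umis maximum total UMIs (default 20000).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_mito = 0.05, min_genes = 200,
                          max_genes = 4000, max_umis = 20000) {
  assert_proportion(max_mito, "max_mito")
  assert_scalar_num(min_genes, "min_genes", lower = 1, integer = TRUE)
  assert_scalar_num(max_genes, "max_genes", lower = 1, integer = TRUE)
  assert_scalar_num(max_umis, "max_umis", lower = 1, integer = TRUE)
  if (min_genes >= max_genes)
    stop_field("min_genes", "must be < max_genes")
  structure(list(max_mito = max_mito, min_genes = min_genes,
                 max_genes = max_genes, max_umis = max_umis),
            class = "qc_thresholds")
}

#' Compute per-cell QC metrics
#'
#' Detection is UMIs > 0.  The mitochondrial fraction of an all-zero cell is
#' defined as 0.
#'
#' @param cm a [fru_counts].
#' @param mito_prefix gene-id prefix identifying mitochondrial genes
#'   (fly nomenclature default `"mt:"`).
#' @param thresholds a [qc_thresholds]; used to fill the `pass`/`fail_reasons`
#'   columns.
#' @return A data.frame with one row per cell: `barcode`, `n_genes_detected`,
#'   `n_umis`, `mito_fraction`, `pass`, `fail_reasons` (comma-separated subset
#'   of `mito`, `low_genes`, `high_genes`, `high_umis`; empty iff `pass`).
#' @export
compute_qc <- function(cm, mito_prefix = "mt:", thresholds = qc_thresholds()) {
  stopifnot(inherits(cm, "fru_counts"), inherits(thresholds, "qc_thresholds"))
  counts <- cm$counts
  n_umis <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito_idx <- startsWith(cm$gene_ids, mito_prefix)
  mito_umis <- if (any(mito_idx))
    Matrix::colSums(counts[mito_idx, , drop = FALSE]) else numeric(ncol(counts))
  mito_fraction <- ifelse(n_umis > 0, mito_umis / n_umis, 0)
  fails <- cbind(mito = mito_fraction > thresholds$max_mito,
                 low_genes = n_genes < thresholds$min_genes,
                 high_genes = n_genes > thresholds$max_genes,
                 high_umis = n_umis > thresholds$max_umis)
  reasons <- apply(fails, 1L, function(f) paste(colnames(fails)[f], collapse = ","))
  data.frame(barcode = cm$barcodes,
             n_genes_detected = as.integer(n_genes),
             n_umis = as.integer(n_umis),
             mito_fraction = as.numeric(mito_fraction),
             pass = !apply(fails, 1L, any),
             fail_reasons = reasons,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter cells on QC thresholds
#'
#' Removes exactly the cells whose QC metrics are strictly beyond the
#' thresholds (see [qc_thresholds] for the boundary semantics).  Filtering is
#' idempotent and partitions the input: removed and kept cells are disjoint
#' and jointly exhaustive.
#'
#' @inheritParams compute_qc
#' @return A list with `cm` (a [fru_counts] of passing cells) and `qc` (the
#'   full QC report including removed cells).
#' @export
filter_cells <- function(cm, thresholds = qc_thresholds(), mito_prefix = "mt:") {
  qc <- compute_qc(cm, mito_prefix = mito_prefix, thresholds = thresholds)
  if (!any(qc$pass)) warning("no cells pass the QC thresholds")
  list(cm = subset_cells(cm, qc$pass), qc = qc)
}

#' Classify cells as neurons by canonical neuronal genes
#'
#' A cell is called a neuron when it has at least one UMI for any of the
#' listed genes (pan-neuronal markers elav, nSyb and noe by default).
#'
#' @param cm a [fru_counts].
#' @param neuron_genes gene ids; members missing from the matrix trigger a
#'   warning and are treated as all-zero.
#' @return A list: `is_neuron` (named logical per cell), `n_neurons`,
#'   `fraction` (raw fraction of cells classified as neurons) and
#'   `percent` (the same on a 0-100 scale).
#' @export
classify_neurons <- function(cm, neuron_genes = c("elav", "nSyb", "noe")) {
  stopifnot(inherits(cm, "fru_counts"))
  present <- neuron_genes %in% cm$gene_ids
  if (!all(present))
    warning(sprintf("neuron gene(s) not in matrix: %s",
                    paste(neuron_genes[!present], collapse = ", ")))
  genes <- neuron_genes[present]
  is_neuron <- if (length(genes))
    Matrix::colSums(cm$counts[genes, , drop = FALSE] > 0) > 0
  else rep(FALSE, ncol(cm$counts))
  is_neuron <- setNames(as.logical(is_neuron), cm$barcodes)
  frac <- mean(is_neuron)
  list(is_neuron = is_neuron, n_neurons = sum(is_neuron),
       fraction = frac, percent = 100 * frac)
}
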