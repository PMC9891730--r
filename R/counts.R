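#' Construct a labelled UMI count matrix
#'
#' The central container of the pipeline: a sparse genes x cells matrix of
#' non-negative integer UMI counts together with per-cell sex and replicate
#' labels.  All downstream stages (QC, normalization, clustering, markers,
#' sex-bias classification) operate on this object.
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts;
#'   coerced to a sparse `dgCMatrix`.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   If `NULL`, taken from `rownames(counts)`.
#' @param barcodes character vector of unique cell barcodes, one per column.
#'   If `NULL`, taken from `colnames(counts)`.
#' @param cell_meta data.frame with one row per cell carrying at least
#'   `sex` (`"male"`/`"female"`) and `replicate` columns.
#' @return An object of class `fru_counts`: a list with elements `counts`
#'   (dgCMatrix), `gene_ids`, `barcodes` and `cell_meta`.
#' @export
fru_counts <- function(counts, gene_ids = NULL, barcodes = NULL, cell_meta) {
  if (!inherits(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  gene_ids <- gene_ids %||% rownames(counts)
  barcodes <- barcodes %||% colnames(counts)
  if (is.null(gene_ids)) stop_field("gene_ids", "missing and counts has no rownames")
  if (is.null(barcodes)) stop_field("barcodes", "missing and counts has no colnames")
  if (length(gene_ids) != nrow(counts))
    stop_field("gene_ids", sprintf("%d ids but %d matrix rows",
                                   length(gene_ids), nrow(counts)))
  if (length(barcodes) != ncol(counts))
    stop_field("barcodes", sprintf("%d barcodes but %d matrix columns",
                                   length(barcodes), ncol(counts)))
  if (anyDuplicated(barcodes)) stop_field("barcodes", "must be unique")
  if (anyDuplicated(gene_ids)) stop_field("gene_ids", "must be unique")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop_field("counts", "must be non-negative integers (UMIs)")
  if (!is.data.frame(cell_meta) || nrow(cell_meta) != ncol(counts))
    stop_field("cell_meta", "must be a data.frame with one row per cell")
  for (col in c("sex", "replicate")) {
    if (is.null(cell_meta[[col]]))
      stop_field("cell_meta", sprintf("missing required column '%s'", col))
  }
  sex <- as.character(cell_meta$sex)
  bad <- which(is.na(sex) | !(sex %in% c("male", "female")))
  if (length(bad))
    stop_field("cell_meta", sprintf(
      "sex must be 'male' or 'female'; first offending barcode: %s",
      barcodes[bad[1L]]))
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(
    list(counts = counts, gene_ids = gene_ids, barcodes = barcodes,
         cell_meta = data.frame(barcode = barcodes, sex = sex,
                                replicate = cell_meta$replicate,
                                stringsAsFactors = FALSE)),
    class = "fru_counts")
}

#' @export
print.fru_counts <- function(x, ...) {
  cat(sprintf("fru_counts: %d genes x %d cells (%d male, %d female)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$cell_meta$sex == "male"),
              sum(x$cell_meta$sex == "female")))
  invisible(x)
}

#' @export
dim.fru_counts <- function(x) dim(x$counts)

#' Subset a count matrix to a set of cells
#'
#' Cells are removed whole; counts are never thinned.
#'
#' @param cm a [fru_counts] object.
#' @param cells barcodes, or a logical/integer index over columns.
#' @return A [fru_counts] restricted to the selected cells, in the given order.
#' @export
subset_cells <- function(cm, cells) {
  stopifnot(inherits(cm, "fru_counts"))
  if (is.character(cells)) {
    idx <- match(cells, cm$barcodes)
    if (anyNA(idx)) stop_field("cells", "unknown barcode(s)")
  } else if (is.logical(cells)) {
    if (length(cells) != ncol(cm$counts))
      stop_field("cells", "logical index must have one entry per cell")
    idx <- which(cells)
  } else {
    idx <- as.integer(cells)
    if (any(idx < 1L) || any(idx > ncol(cm$counts)))
      stop_field("cells", "index out of range")
  }
  fru_counts(cm$counts[, idx, drop = FALSE],
             gene_ids = cm$gene_ids,
             barcodes = cm$barcodes[idx],
             cell_meta = cm$cell_meta[idx, , drop = FALSE])
}
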