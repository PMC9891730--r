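#' Pairwise gene-gene correlation across single cells
#'
#' Correlations are computed over all (or a subset of) cells on the
#' log-normalized values by default.  Constant genes have undefined
#' correlations; these are reported as `NA` with a warning rather than 0.
#'
#' @param nm genes x cells matrix (log-normalized from [log_normalize()], or
#'   raw counts if that is the scale wanted).
#' @param genes gene ids to correlate (>= 2); unknown ids are an error.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param cells optional cell subset (barcodes or indices).
#' @return A list of class `correlation_matrix`: `genes`, `r` (symmetric,
#'   unit diagonal), `p` (two-sided correlation-test p-values, `NA` on the
#'   diagonal), `method`, `n_cells`.
#' @export
pairwise_correlation <- function(nm, genes, method = c("pearson", "spearman"),
                                 cells = NULL) {
  method <- match.arg(method)
  missing <- setdiff(genes, rownames(nm))
  if (length(missing))
    stop_field("genes", sprintf("not in matrix: %s",
                                paste(missing, collapse = ", ")))
  if (!is.null(cells)) nm <- nm[, cells, drop = FALSE]
  if (ncol(nm) < 3) stop_field("nm", "need at least 3 cells")
  x <- t(as.matrix(nm[genes, , drop = FALSE]))
  const <- apply(x, 2L, function(v) var(v) == 0)
  if (any(const))
    warning(sprintf("constant gene(s), correlation undefined: %s",
                    paste(genes[const], collapse = ", ")))
  r <- suppressWarnings(cor(x, method = method))
  diag(r) <- ifelse(const, NA_real_, 1)
  p <- matrix(NA_real_, length(genes), length(genes),
              dimnames = dimnames(r))
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i < j && !const[i] && !const[j]) {
      pv <- suppressWarnings(
        cor.test(x[, i], x[, j], method = method, exact = FALSE)$p.value)
      p[i, j] <- p[j, i] <- pv
    }
  }
  structure(list(genes = genes, r = r, p = p, method = method,
                 n_cells = nrow(x)),
            class = "correlation_matrix")
}

#' Exclusive overlap proportions for a gene trio
#'
#' Cells are classed by which of the three genes they express (UMIs > 0);
#' the seven exclusive regions (A only, B only, C only, AB, AC, BC, ABC) are
#' reported as fractions of cells expressing at least one of the trio.
#'
#' @param cm a [fru_counts].
#' @param trio character vector of exactly three gene ids.
#' @return A list: `proportions` (named, summing to 1 over the expressing
#'   denominator; all `NA` with a warning when no cell expresses any),
#'   `n_expressing` (denominator), `counts` (region cell counts).
#' @export
overlap_proportions <- function(cm, trio) {
  stopifnot(inherits(cm, "fru_counts"))
  if (length(trio) != 3) stop_field("trio", "need exactly 3 genes")
  missing <- setdiff(trio, cm$gene_ids)
  if (length(missing))
    stop_field("trio", sprintf("not in matrix: %s",
                               paste(missing, collapse = ", ")))
  memb <- t(as.matrix(cm$counts[trio, , drop = FALSE] > 0))
  key <- memb %*% c(1, 2, 4)
  regions <- c("A" = 1, "B" = 2, "C" = 4, "AB" = 3, "AC" = 5, "BC" = 6,
               "ABC" = 7)
  counts <- vapply(regions, function(kk) sum(key == kk), numeric(1))
  n_expr <- sum(counts)
  props <- if (n_expr > 0) counts / n_expr else {
    warning("no cell expresses any gene of the trio; proportions undefined")
    rep(NA_real_, length(counts)) |> setNames(names(counts))
  }
  list(proportions = props, n_expressing = n_expr, counts = counts,
       trio = setNames(trio, c("A", "B", "C")))
}

#' Aminergic / fast-neurotransmitter co-transmission proportions
#'
#' For each aminergic class (membership: any member gene with UMIs > 0) and
#' each fast-acting neurotransmitter (FAN) class, the per-sex proportion of
#' aminergic cells co-expressing the FAN gene set.
#'
#' @param cm a [fru_counts].
#' @param aminergic_sets,fan_sets named lists of gene-id vectors; defaults
#'   follow the standard fly vocabularies (dopaminergic DAT/ple, serotonergic
#'   SerT, tyraminergic/octopaminergic Tdc2; cholinergic ChAT/VAChT,
#'   GABAergic Gad1/VGAT, glutamatergic VGlut).
#' @param by_sex split proportions by sex (default TRUE).
#' @return A data.frame: `aminergic`, `fan`, `sex` (or `"all"`), `n_aminergic`,
#'   `n_co`, `proportion` (`NA`, flagged by `defined = FALSE`, when a sex has
#'   zero aminergic cells of that class).
#' @export
cotransmission <- function(cm,
                           aminergic_sets = list(
                             dopaminergic = c("DAT", "ple"),
                             serotonergic = "SerT",
                             tyr_oct = "Tdc2"),
                           fan_sets = list(
                             cholinergic = c("ChAT", "VAChT"),
                             gabaergic = c("Gad1", "VGAT"),
                             glutamatergic = "VGlut"),
                           by_sex = TRUE) {
  am <- classify_cells_by_sets(cm, aminergic_sets)$flags
  fan <- classify_cells_by_sets(cm, fan_sets)$flags
  sexes <- if (by_sex) c("male", "female") else "all"
  sex_vec <- cm$cell_meta$sex
  rows <- list()
  for (a in colnames(am)) for (f in colnames(fan)) for (s in sexes) {
    in_sex <- if (s == "all") rep(TRUE, length(sex_vec)) else sex_vec == s
    n_am <- sum(am[, a] & in_sex)
    n_co <- sum(am[, a] & fan[, f] & in_sex)
    rows[[length(rows) + 1L]] <- data.frame(
      aminergic = a, fan = f, sex = s, n_aminergic = n_am, n_co = n_co,
      proportion = if (n_am > 0) n_co / n_am else NA_real_,
      defined = n_am > 0, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
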