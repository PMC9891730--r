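# Shared two-group differential-expression engine.
#
# For each gene: detection fractions (raw UMIs > 0) in the two groups,
# natural-log fold change on de-logged means with pseudocount 1
#   log_fc = ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1)),
# and a two-sided Wilcoxon rank-sum test on the log-normalized values.
# Genes are pre-filtered before testing: detection in at least one group
# must reach min_pct and log_fc must reach logfc_threshold (enriched in
# group 1).  Bonferroni correction multiplies by the total number of genes
# in the matrix.
de_two_groups <- function(nm, counts, idx_in, idx_out, min_pct, logfc_threshold,
                          n_genes_total) {
  pct_in <- Matrix::rowMeans(counts[, idx_in, drop = FALSE] > 0)
  pct_out <- Matrix::rowMeans(counts[, idx_out, drop = FALSE] > 0)
  mean_in <- Matrix::rowMeans(expm1(nm[, idx_in, drop = FALSE]))
  mean_out <- Matrix::rowMeans(expm1(nm[, idx_out, drop = FALSE]))
  log_fc <- log((mean_in + 1) / (mean_out + 1))
  keep <- which(pmax(pct_in, pct_out) >= min_pct & log_fc >= logfc_threshold &
                  log_fc > 0)
  if (!length(keep))
    return(data.frame(gene = character(), p_raw = numeric(),
                      p_bonferroni = numeric(), log_fc = numeric(),
                      pct_in = numeric(), pct_out = numeric(),
                      stringsAsFactors = FALSE))
  p_raw <- vapply(keep, function(g) {
    x <- nm[g, idx_in]
    y <- nm[g, idx_out]
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
  }, numeric(1))
  data.frame(gene = rownames(nm)[keep],
             p_raw = p_raw,
             p_bonferroni = pmin(1, p_raw * n_genes_total),
             log_fc = log_fc[keep],
             pct_in = pct_in[keep], pct_out = pct_out[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Find per-cluster enriched marker genes
#'
#' For every cluster, each gene's log-normalized expression in the cluster is
#' compared with its expression in all remaining cells by a two-sided
#' Wilcoxon rank-sum test.  Only positively enriched genes passing the
#' detection-fraction and natural-log fold-change pre-filters are tested, and
#' only genes passing the significance rule are retained as markers.
#'
#' @param cm a [fru_counts] (raw counts define detection fractions).
#' @param nm the matching log-normalized matrix from [log_normalize()].
#' @param labels per-cell cluster labels (a `fru_clusters` or a named/plain
#'   vector aligned with the cells).
#' @param min_pct minimum detection fraction in at least one of the two
#'   groups (default 0.25).
#' @param logfc_threshold minimum natural-log fold change (default 0.25).
#' @param alpha significance level (default 0.05).
#' @param p_filter which p-value column the significance rule uses:
#'   `"raw"` (default) or `"bonferroni"`.
#' @param min_cells clusters with fewer cells are skipped with a warning.
#' @return A data.frame of class `marker_table` with columns `cluster`,
#'   `gene`, `p_raw`, `p_bonferroni`, `log_fc`, `pct_in`, `pct_out`;
#'   thresholds are recorded in the `params` attribute.
#' @export
find_markers <- function(cm, nm, labels, min_pct = 0.25,
                         logfc_threshold = 0.25, alpha = 0.05,
                         p_filter = c("raw", "bonferroni"), min_cells = 3) {
  p_filter <- match.arg(p_filter)
  labels <- label_vector(labels, cm)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2)
    stop_field("labels", "need at least 2 clusters to find markers")
  n_genes_total <- nrow(nm)
  out <- lapply(clusters, function(cl) {
    idx_in <- which(labels == cl)
    if (length(idx_in) < min_cells) {
      warning(sprintf("cluster %s has < %d cells; skipped", cl, min_cells))
      return(NULL)
    }
    d <- de_two_groups(nm, cm$counts, idx_in, which(labels != cl),
                       min_pct, logfc_threshold, n_genes_total)
    if (nrow(d)) cbind(cluster = cl, d) else NULL
  })
  tab <- do.call(rbind, out)
  if (is.null(tab))
    tab <- data.frame(cluster = integer(), gene = character(),
                      p_raw = numeric(), p_bonferroni = numeric(),
                      log_fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), stringsAsFactors = FALSE)
  p_col <- if (p_filter == "raw") tab$p_raw else tab$p_bonferroni
  tab <- tab[p_col < alpha, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "params") <- list(min_pct = min_pct,
                              logfc_threshold = logfc_threshold,
                              alpha = alpha, p_filter = p_filter,
                              n_genes_tested = n_genes_total)
  class(tab) <- c("marker_table", class(tab))
  tab
}

#' Sex-differential expression within each cluster
#'
#' Within every cluster containing at least `min_cells` cells of each sex,
#' male and female cells are compared with the same test and filters as
#' [find_markers()]; genes enriched in either direction are reported.
#'
#' @inheritParams find_markers
#' @param sex per-cell sex labels; defaults to `cm$cell_meta$sex`.
#' @return A data.frame with columns `cluster`, `gene`, `direction`
#'   (`"male"`/`"female"`), `p_raw`, `p_bonferroni`, `log_fc` (positive, in
#'   the favoured direction), `pct_in`, `pct_out`.  Skipped clusters and the
#'   reason are recorded in the `skipped` attribute.
#' @export
find_sex_de_within_cluster <- function(cm, nm, labels, sex = NULL,
                                       min_pct = 0.25, logfc_threshold = 0.25,
                                       alpha = 0.05,
                                       p_filter = c("raw", "bonferroni"),
                                       min_cells = 3) {
  p_filter <- match.arg(p_filter)
  labels <- label_vector(labels, cm)
  sex <- sex %||% cm$cell_meta$sex
  n_genes_total <- nrow(nm)
  skipped <- character()
  out <- list()
  for (cl in sort(unique(labels))) {
    idx_m <- which(labels == cl & sex == "male")
    idx_f <- which(labels == cl & sex == "female")
    if (length(idx_m) < min_cells || length(idx_f) < min_cells) {
      skipped[as.character(cl)] <- sprintf(
        "only %d male / %d female cells", length(idx_m), length(idx_f))
      next
    }
    dm <- de_two_groups(nm, cm$counts, idx_m, idx_f, min_pct,
                        logfc_threshold, n_genes_total)
    df <- de_two_groups(nm, cm$counts, idx_f, idx_m, min_pct,
                        logfc_threshold, n_genes_total)
    if (nrow(dm)) out[[length(out) + 1L]] <- cbind(cluster = cl,
                                                   direction = "male", dm)
    if (nrow(df)) out[[length(out) + 1L]] <- cbind(cluster = cl,
                                                   direction = "female", df)
  }
  tab <- do.call(rbind, out)
  if (is.null(tab))
    tab <- data.frame(cluster = integer(), direction = character(),
                      gene = character(), p_raw = numeric(),
                      p_bonferroni = numeric(), log_fc = numeric(),
                      pct_in = numeric(), pct_out = numeric(),
                      stringsAsFactors = FALSE)
  p_col <- if (p_filter == "raw") tab$p_raw else tab$p_bonferroni
  tab <- tab[p_col < alpha, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "skipped") <- skipped
  attr(tab, "params") <- list(min_pct = min_pct,
                              logfc_threshold = logfc_threshold,
                              alpha = alpha, p_filter = p_filter,
                              n_genes_tested = n_genes_total)
  tab
}

#' Top markers per cluster by log fold-change
#'
#' @param table a `marker_table` from [find_markers()].
#' @param n markers per cluster (clusters with fewer return all).
#' @param rank_by ranking column (default `log_fc`, decreasing); ties broken
#'   by increasing `p_raw`, then gene id.
#' @return The subsetted table, ordered by cluster then rank.
#' @export
top_markers <- function(table, n = 5, rank_by = "log_fc") {
  stopifnot(nrow(table) >= 0, rank_by %in% names(table))
  if (!nrow(table)) return(table)
  parts <- lapply(split(seq_len(nrow(table)), table$cluster), function(ix) {
    d <- table[ix, , drop = FALSE]
    d <- d[order(-d[[rank_by]], d$p_raw, d$gene), , drop = FALSE]
    head(d, n)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# accept fru_clusters, named vector or plain vector
label_vector <- function(labels, cm) {
  if (inherits(labels, "fru_clusters")) labels <- labels$labels
  if (!is.null(names(labels)) && inherits(cm, "fru_counts")) {
    if (all(cm$barcodes %in% names(labels))) labels <- labels[cm$barcodes]
  }
  if (length(labels) != ncol(cm$counts))
    stop_field("labels", "must provide one label per cell")
  unname(labels)
}
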