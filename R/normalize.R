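#' Log-normalize a count matrix
#'
#' Counts-per-scale-factor followed by natural `log1p`:
#' `value = ln(1 + count / cell_total * scale_factor)`.  Zeros map to zeros,
#' so sparsity is preserved, and the transform is monotone within a cell.
#' Cells with zero total counts yield an all-zero column (with a warning).
#'
#' @param cm a [fru_counts].
#' @param scale_factor library-size target (default 10,000).
#' @return A sparse genes x cells `dgCMatrix` of normalized values with a
#'   `scale_factor` attribute.
#' @export
log_normalize <- function(cm, scale_factor = 1e4) {
  stopifnot(inherits(cm, "fru_counts"))
  assert_scalar_num(scale_factor, "scale_factor", lower = 0, strict_lower = TRUE)
  totals <- Matrix::colSums(cm$counts)
  if (any(totals == 0))
    warning(sprintf("%d cell(s) with zero total counts normalized to zeros",
                    sum(totals == 0)))
  inv <- ifelse(totals > 0, scale_factor / totals, 0)
  nm <- cm$counts %*% Matrix::Diagonal(x = inv)
  nm@x <- log1p(nm@x)
  dimnames(nm) <- dimnames(cm$counts)
  nm <- methods::as(nm, "CsparseMatrix")
  attr(nm, "scale_factor") <- scale_factor
  nm
}

#' Select highly variable genes by trend-corrected standardized variance
#'
#' Per-gene raw-count mean and variance are computed; a loess trend of
#' log10(variance) on log10(mean) predicts the expected variance at each
#' gene's mean; counts are standardized with the trend-predicted standard
#' deviation (clipped at `sqrt(n_cells)`), and genes are ranked by the
#' variance of these standardized counts.  Deterministic, ties broken by
#' gene id.
#'
#' @param cm a [fru_counts] (raw counts are used for the mean-variance trend).
#' @param n number of genes to return (all genes, with a warning, if the
#'   matrix has fewer).
#' @param loess_span span of the mean-variance trend fit.
#' @return Character vector of `n` gene ids ordered by decreasing
#'   standardized variance, with the scores in the `standardized_variance`
#'   attribute and `method = "vst"` recorded in the `method` attribute.
#' @export
select_hvgs <- function(cm, n = 2000, loess_span = 0.3) {
  stopifnot(inherits(cm, "fru_counts"))
  assert_scalar_num(n, "n", lower = 1, integer = TRUE)
  counts <- cm$counts
  n_cells <- ncol(counts)
  mu <- Matrix::rowMeans(counts)
  v <- Matrix::rowMeans(counts^2) * n_cells / (n_cells - 1) -
    mu^2 * n_cells / (n_cells - 1)
  score <- numeric(nrow(counts))
  usable <- v > 0 & mu > 0
  if (sum(usable) >= 5) {
    fit <- loess(log10(v[usable]) ~ log10(mu[usable]), span = loess_span,
                 degree = 2)
    sd_exp <- sqrt(10^predict(fit))
    clip <- sqrt(n_cells)
    dense <- as.matrix(counts[usable, , drop = FALSE])
    z <- (dense - mu[usable]) / sd_exp
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    score[usable] <- apply(z, 1L, var)
  } else {
    score[usable] <- v[usable]          # too few genes for a trend fit
  }
  if (n > nrow(counts)) {
    warning(sprintf("requested %d HVGs but only %d genes; returning all",
                    n, nrow(counts)))
    n <- nrow(counts)
  }
  ord <- order(-score, cm$gene_ids)
  out <- cm$gene_ids[ord][seq_len(n)]
  attr(out, "standardized_variance") <- setNames(score, cm$gene_ids)[out]
  attr(out, "method") <- "vst"
  out
}

# Center/scale rows of the normalized matrix for the HVG set, clipping
# extreme standardized values (common practice so a handful of cells cannot
# dominate a component).  Returns a dense cells x genes matrix.
scale_for_pca <- function(nm, hvgs, clip = 10) {
  x <- t(as.matrix(nm[hvgs, , drop = FALSE]))
  x <- scale(x, center = TRUE, scale = TRUE)
  x[is.na(x)] <- 0                      # constant genes
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  x
}

# Truncated PCA on a dense cells x genes matrix (already scaled).
# irlba for large problems, base svd otherwise.
pca_scores <- function(x, n_pcs) {
  n_pcs <- min(n_pcs, dim(x) - 1L)
  if (min(dim(x)) > 3 * n_pcs + 10) {
    s <- irlba::irlba(x, nv = n_pcs)
  } else {
    s <- svd(x, nu = n_pcs, nv = n_pcs)
    s$d <- s$d[seq_len(n_pcs)]
  }
  scores <- s$u %*% diag(s$d, n_pcs, n_pcs)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  loadings <- s$v
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- colnames(scores)
  var_exp <- s$d^2 / (nrow(x) - 1)
  list(scores = scores, loadings = loadings, variance_explained = var_exp)
}

# stopping rule: largest k such that PCs 1..k are all significant and the
# next PC (if any) is not
select_n_pcs <- function(p, alpha = 0.05) {
  sig <- p < alpha
  if (!length(sig) || !sig[1]) return(0L)
  first_ns <- which(!sig)
  if (!length(first_ns)) length(sig) else first_ns[1] - 1L
}

#' PCA with jackstraw significance for the principal components
#'
#' Runs PCA on the scaled HVG submatrix, then assesses PC significance by the
#' jackstraw permutation scheme: in each of `n_reps` replicates a random
#' proportion `prop` of the HVGs have their values permuted independently
#' across cells, PCA is recomputed on the full (part-permuted) matrix, and
#' the permuted genes' loadings form the null distribution for that PC.
#' Each gene receives an empirical p-value per PC from the pooled null; the
#' PC-level p-value asks, by a one-sided proportion test, whether more genes
#' have small p-values than the uniform expectation.
#'
#' Gene-level p-values within one PC are positively dependent (every gene
#' helped fit the same component), which makes the proportion test alone
#' anticonservative on unstructured data, noticeably so at a few hundred
#' genes.  A parallel-analysis eigenvalue guard therefore backs the call:
#' a PC also has to exceed the `1 - alpha` quantile of its eigenvalue under
#' full column-wise permutation of the scaled matrix.  A PC counts as
#' significant only when both checks agree, and the number of PCs retained
#' is counted up to the first non-significant PC.
#'
#' @param nm normalized matrix from [log_normalize()].
#' @param hvgs gene ids to use (from [select_hvgs()]).
#' @param max_pcs number of PCs to compute and test.
#' @param prop proportion of HVGs permuted per replicate.
#' @param n_reps number of permutation replicates.
#' @param alpha PC-level significance level.
#' @param seed integer seed (permutations are the only randomness).
#' @param min_pcs if the stopping rule selects fewer than `min_pcs`
#'   components, `n_selected` is raised to `min_pcs` with a warning; with the
#'   default 0, a selection of zero PCs is returned as-is (also with a
#'   warning) and downstream clustering will refuse to run.
#' @param gene_thresh gene-level p-value cutoff fed to the proportion test.
#' @param n_eig_perms full-permutation replicates for the eigenvalue guard
#'   (0 disables the guard).
#' @return A list of class `fru_pca`: `scores` (cells x max_pcs),
#'   `loadings`, `variance_explained`, `jackstraw_p` (per PC),
#'   `eig_null_quantile` (per PC), `n_selected`, plus the parameters used.
#' @export
jackstraw_select_pcs <- function(nm, hvgs, max_pcs = 20, prop = 0.01,
                                 n_reps = 100, alpha = 0.05, seed = 1,
                                 min_pcs = 0, gene_thresh = 0.05,
                                 n_eig_perms = 30) {
  assert_scalar_num(max_pcs, "max_pcs", lower = 1, integer = TRUE)
  assert_proportion(prop, "prop")
  assert_scalar_num(n_reps, "n_reps", lower = 1, integer = TRUE)
  assert_proportion(alpha, "alpha")
  assert_scalar_num(seed, "seed", integer = TRUE)
  if (max_pcs > min(dim(nm)) - 1L)
    stop_field("max_pcs", "must be <= min(genes, cells) - 1")
  hvgs <- as.character(hvgs)
  x <- scale_for_pca(nm, hvgs)
  real <- pca_scores(x, max_pcs)
  n_pcs <- ncol(real$scores)
  n_genes <- length(hvgs)
  k <- max(1L, round(prop * n_genes))

  set.seed(seed)
  null_load <- matrix(NA_real_, n_reps * k, n_pcs)
  for (r in seq_len(n_reps)) {
    perm_genes <- sample.int(n_genes, k)
    xp <- x
    for (g in perm_genes) xp[, g] <- xp[sample.int(nrow(x)), g]
    pp <- pca_scores(xp, n_pcs)
    null_load[(r - 1L) * k + seq_len(k), ] <- abs(pp$loadings[perm_genes, ,
                                                              drop = FALSE])
  }
  obs <- abs(real$loadings)
  gene_p <- matrix(NA_real_, n_genes, n_pcs)
  for (j in seq_len(n_pcs)) {
    nl <- sort(null_load[, j])
    # empirical upper-tail p with add-one correction
    gene_p[, j] <- (length(nl) - findInterval(obs[, j], nl) + 1) /
      (length(nl) + 1)
  }
  pc_p <- vapply(seq_len(n_pcs), function(j) {
    xct <- sum(gene_p[, j] <= gene_thresh)
    prop.test(xct, n_genes, p = gene_thresh,
              alternative = "greater")$p.value
  }, numeric(1))
  # parallel-analysis eigenvalue guard: a PC must also beat the 1 - alpha
  # quantile of its eigenvalue under full column-wise permutation
  eig_q <- rep(-Inf, n_pcs)
  if (n_eig_perms > 0) {
    null_eig <- matrix(NA_real_, n_eig_perms, n_pcs)
    for (b in seq_len(n_eig_perms)) {
      xp <- apply(x, 2L, sample)
      null_eig[b, ] <- pca_scores(xp, n_pcs)$variance_explained
    }
    eig_q <- apply(null_eig, 2L, quantile, probs = 1 - alpha, names = FALSE)
  }
  p_comb <- ifelse(real$variance_explained > eig_q, pc_p, 1)
  n_sel <- select_n_pcs(p_comb, alpha)
  if (n_sel < min_pcs) {
    warning(sprintf("jackstraw selected %d PCs; forcing min_pcs = %d",
                    n_sel, min_pcs))
    n_sel <- as.integer(min_pcs)
  } else if (n_sel == 0L) {
    warning("jackstraw selected 0 significant PCs; downstream clustering ",
            "requires at least 1 (use min_pcs to force a floor)")
  }
  structure(list(scores = real$scores, loadings = real$loadings,
                 variance_explained = real$variance_explained,
                 jackstraw_p = pc_p, eig_null_quantile = eig_q,
                 n_selected = as.integer(n_sel),
                 hvgs = hvgs,
                 params = list(max_pcs = max_pcs, prop = prop,
                               n_reps = n_reps, alpha = alpha, seed = seed,
                               gene_thresh = gene_thresh,
                               n_eig_perms = n_eig_perms)),
            class = "fru_pca")
}
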