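# Small programmatic fixtures shared across test files.

# A tiny fru_counts built from a dense matrix; equal column totals are easy
# to arrange so normalized values stay monotone in the raw counts.
toy_counts <- function(mat, sex = NULL, replicate = NULL) {
  n <- ncol(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(n))
  fru_counts(mat,
             cell_meta = data.frame(
               sex = sex %||% rep(c("male", "female"), length.out = n),
               replicate = replicate %||% rep("rep1", n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-cluster count matrix where `gene` takes the requested per-cell counts
# and a filler gene tops every cell up to `total`, so the log-normalized
# values of `gene` preserve the ordering of `counts`.
two_group_counts <- function(counts, labels, total = NULL) {
  total <- total %||% (max(counts) + 5)
  mat <- rbind(g = counts, filler = total - counts)
  toy_counts(mat)
}

# Exhaustive-enumeration oracle for the two-sided Wilcoxon rank-sum p-value
# (no ties): enumerate every assignment of the pooled values to group 1,
# using the same two-sided rule as the exact distribution (double the
# attained tail, capped at 1).
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2L, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  p <- if (w_obs > mu) mean(w_all >= w_obs) else mean(w_all <= w_obs)
  min(1, 2 * p)
}

# Normal-approximation oracle with tie correction and continuity correction,
# mirroring the standard large-sample rank-sum reference.
normal_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  z <- w - n1 * n2 / 2
  sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  z <- (z - sign(z) * 0.5) / sigma
  2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE), 0.5)
}

# Independent dense recomputation of per-cell QC metrics and the set of
# cells violating the default thresholds (strict inequalities).
naive_qc_violations <- function(cm, mito_prefix = "mt:",
                                th = list(max_mito = 0.05, min_genes = 200,
                                          max_genes = 4000, max_umis = 20000)) {
  m <- as.matrix(cm$counts)
  viol <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    umis <- sum(m[, j])
    genes <- sum(m[, j] > 0)
    mito <- if (umis > 0)
      sum(m[startsWith(rownames(m), mito_prefix), j]) / umis else 0
    viol[j] <- mito > th$max_mito || genes < th$min_genes ||
      genes > th$max_genes || umis > th$max_umis
  }
  cm$barcodes[viol]
}

# Naive independent re-evaluation of the cluster annotation rules for one
# cluster, written directly from the rule statements.
naive_annotate <- function(markers, expressed, rules) {
  labs <- character()
  if (any(rules$hox %in% markers)) labs <- c(labs, "VNC")
  core <- any(rules$kc_core %in% markers)
  axon <- any(rules$kc_axon %in% markers)
  trio <- any(rules$kc_gamma %in% markers)
  if (core && axon) {
    labs <- c(labs, if (trio) "KC_gamma" else "KC_ab")
  } else {
    low_a <- all(rules$kc_axon %in% markers) &&
      any(rules$kc_core %in% setdiff(expressed, markers))
    low_b <- trio && sum(c("Fas2", "Dop1R2") %in% markers) == 1
    if (low_a || low_b) labs <- c(labs, "KC")
  }
  if (any(rules$cholinergic %in% markers)) labs <- c(labs, "cholinergic")
  if (any(rules$gabaergic %in% markers)) labs <- c(labs, "gabaergic")
  if (any(rules$glutamatergic %in% markers)) labs <- c(labs, "glutamatergic")
  if (any(rules$dopaminergic %in% markers)) labs <- c(labs, "dopaminergic")
  if (any(rules$serotonergic %in% markers)) labs <- c(labs, "serotonergic")
  if (any(rules$tyr_oct %in% markers)) labs <- c(labs, "tyr_oct")
  if (any(rules$aminergic %in% markers)) labs <- c(labs, "aminergic")
  if (sum(rules$circadian %in% markers) >= 2) labs <- c(labs, "circadian")
  if (length(rules$neuropeptides) && any(rules$neuropeptides %in% markers))
    labs <- c(labs, "neuropeptide")
  if (length(rules$receptors) && any(rules$receptors %in% markers))
    labs <- c(labs, "receptor")
  sort(labs)
}

# Brute-force sleep oracle: a minute is asleep iff it lies inside some
# all-zero window of `win` consecutive minutes; bouts are maximal runs of
# asleep minutes.
naive_sleep <- function(counts, win = 5L) {
  n <- length(counts)
  asleep <- logical(n)
  if (n >= win) {
    for (s in seq_len(n - win + 1L)) {
      if (all(counts[s:(s + win - 1L)] == 0)) asleep[s:(s + win - 1L)] <- TRUE
    }
  }
  r <- rle(asleep)
  list(total = sum(asleep), bouts = sum(r$values),
       bout_lengths = r$lengths[r$values])
}
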