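#' Randomly downsample cells per sex
#'
#' Uniform random subset without replacement within each sex; cells are
#' removed whole (counts are never thinned).
#'
#' @param cm a [fru_counts].
#' @param target_per_sex either a single target applied to every sex whose
#'   total exceeds it, or a named vector (`male =`, `female =`).
#' @param seed integer seed.
#' @return A [fru_counts] with exactly the target number of cells for each
#'   targeted sex (cells keep their original relative order).
#' @export
downsample <- function(cm, target_per_sex, seed = 1) {
  stopifnot(inherits(cm, "fru_counts"))
  assert_scalar_num(seed, "seed", integer = TRUE)
  sex <- cm$cell_meta$sex
  targets <- if (is.null(names(target_per_sex)))
    c(male = min(target_per_sex, sum(sex == "male")),
      female = min(target_per_sex, sum(sex == "female")))
  else target_per_sex
  set.seed(seed)
  keep <- logical(length(sex))
  for (s in names(targets)) {
    idx <- which(sex == s)
    tg <- targets[[s]]
    if (tg > length(idx))
      stop_field("target_per_sex",
                 sprintf("%s target %d exceeds %d available cells",
                         s, tg, length(idx)))
    keep[sort(sample(idx, tg))] <- TRUE
  }
  keep[!(sex %in% names(targets))] <- TRUE
  subset_cells(cm, keep)
}

#' Random cell removal without re-clustering
#'
#' The lighter robustness check: remove cells at random (per sex, to the
#' given targets), keep the original cluster labels, and re-classify the
#' per-cluster sex composition only.
#'
#' @inheritParams downsample
#' @param labels per-cell cluster labels of the full analysis (named by
#'   barcode, or a `fru_clusters`).
#' @param s scaling factor to use; by default recomputed on the kept cells.
#' @param ... passed to [classify_clusters()].
#' @return The `sex_bias_report` for the kept cells under the original
#'   labels.
#' @export
removal_composition <- function(cm, labels, target_per_sex, seed = 1,
                                s = NULL, ...) {
  if (inherits(labels, "fru_clusters")) labels <- labels$labels
  sub <- downsample(cm, target_per_sex, seed = seed)
  lab <- labels[match(sub$barcodes, cm$barcodes)]
  s <- s %||% compute_scaling(sub)
  classify_clusters(cluster_sex_counts(lab, sub), s, ...)
}

#' Mean log-normalized cluster expression profiles
#'
#' @param nm log-normalized matrix.
#' @param labels per-cell cluster labels.
#' @param genes gene universe for the profiles (typically the analysis'
#'   highly variable genes).
#' @return genes x clusters matrix of mean expression.
#' @export
cluster_profiles <- function(nm, labels, genes) {
  if (inherits(labels, "fru_clusters")) labels <- labels$labels
  genes <- intersect(genes, rownames(nm))
  cls <- sort(unique(labels))
  prof <- vapply(cls, function(cl)
    Matrix::rowMeans(nm[genes, labels == cl, drop = FALSE]),
    numeric(length(genes)))
  matrix(prof, nrow = length(genes),
         dimnames = list(genes, as.character(cls)))
}

#' Match query clusters to reference clusters by rank correlation
#'
#' Each query cluster's mean log-normalized profile over the shared variable
#' genes is correlated (Spearman by default, mirroring clustify-style
#' matching) with every reference cluster profile; the query cluster is
#' assigned to the best-correlated reference cluster when the coefficient
#' reaches `cutoff`, and left unassigned otherwise.  Ties break toward the
#' lower reference cluster id.
#'
#' @param ref_profiles,query_profiles genes x clusters matrices from
#'   [cluster_profiles()]; genes are intersected and must share >= 3 members.
#' @param cutoff minimum correlation for an assignment (default 0.5).
#' @param method correlation method (default `"spearman"`; `"pearson"`
#'   available).
#' @return A data.frame of class `cluster_match_table`: `query`,
#'   `best_reference` (`NA` when unassigned), `rho`, `assigned`.
#' @export
match_clusters <- function(ref_profiles, query_profiles, cutoff = 0.5,
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(rownames(ref_profiles), rownames(query_profiles))
  if (length(shared) < 3)
    stop_field("profiles", sprintf("only %d shared genes (need >= 3)",
                                   length(shared)))
  r <- cor(query_profiles[shared, , drop = FALSE],
           ref_profiles[shared, , drop = FALSE], method = method)
  best <- apply(r, 1L, which.max)       # first maximum = lowest ref id
  rho <- r[cbind(seq_len(nrow(r)), best)]
  assigned <- rho >= cutoff
  out <- data.frame(query = rownames(r),
                    best_reference = ifelse(assigned, colnames(r)[best], NA),
                    rho = rho, assigned = assigned,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "params") <- list(cutoff = cutoff, method = method,
                              n_shared_genes = length(shared))
  class(out) <- c("cluster_match_table", class(out))
  out
}

#' Stability of per-cluster sex-bias classes across downsampling runs
#'
#' For each full-data cluster, looks up the matched cluster in every
#' downsampled re-analysis and compares sex-bias classes.
#'
#' @param full_report `sex_bias_report` of the full analysis.
#' @param runs list of runs; each run is a list with elements `match`
#'   (a `cluster_match_table` of downsampled query clusters vs the full
#'   reference) and `report` (the run's `sex_bias_report`).
#' @return data.frame: `cluster`, `full_class`, one `run<i>_class` column per
#'   run (`"unmatched"` when no query cluster mapped to it), `stable`
#'   (class identical across all matched runs and >= 1 matched run),
#'   `changed_runs` (comma-separated run indices that differ).
#' @export
concordance_report <- function(full_report, runs) {
  stopifnot(length(runs) >= 1)
  out <- data.frame(cluster = as.character(full_report$cluster),
                    full_class = full_report$class,
                    stringsAsFactors = FALSE)
  run_classes <- matrix(NA_character_, nrow(out), length(runs))
  for (i in seq_along(runs)) {
    m <- runs[[i]]$match
    rep_i <- runs[[i]]$report
    for (j in seq_len(nrow(out))) {
      q <- m$query[!is.na(m$best_reference) &
                     m$best_reference == out$cluster[j]]
      if (!length(q)) { run_classes[j, i] <- "unmatched"; next }
      # when several query clusters map to one reference, take the best rho
      q <- q[which.max(m$rho[match(q, m$query)])]
      cls <- rep_i$class[as.character(rep_i$cluster) == q]
      run_classes[j, i] <- if (length(cls)) cls else "unmatched"
    }
    out[[paste0("run", i, "_class")]] <- run_classes[, i]
  }
  matched <- run_classes != "unmatched"
  out$stable <- vapply(seq_len(nrow(out)), function(j) {
    cl <- run_classes[j, matched[j, ]]
    length(cl) > 0 && all(cl == out$full_class[j])
  }, logical(1))
  out$changed_runs <- vapply(seq_len(nrow(out)), function(j) {
    diff <- which(matched[j, ] & run_classes[j, ] != out$full_class[j])
    paste(diff, collapse = ",")
  }, character(1))
  out
}
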