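#' Specification for a synthetic UMI count matrix
#'
#' Describes a genes x cells negative-binomial count matrix with planted
#' cluster structure, marker genes, mitochondrial genes, sexes with possibly
#' unequal cell totals, replicate labels, and droplet artifacts (empty
#' droplets, high-mitochondrial cells, multiplets).  The generator emulates
#' the statistical structure a droplet scRNA-seq pipeline assumes, with full
#' ground truth, so every downstream stage can be exercised and scored.
#'
#' @param n_clusters number of planted clusters (>= 1).
#' @param cells_per_cluster_per_sex either a single number (cells per cluster
#'   per sex) or an `n_clusters` x 2 matrix with columns `male`, `female`.
#'   Zeros plant sex-specific clusters.
#' @param n_genes total number of genes, including mitochondrial genes.
#' @param baseline_mean average negative-binomial mean per gene per cell;
#'   per-gene means are drawn around it (see `gene_mean_sdlog`).
#' @param gene_mean_sdlog log-normal spread of per-gene baseline means
#'   (sdlog; 0 gives every gene the same mean).  Real droplet data span
#'   orders of magnitude in per-gene abundance; the default 0.5 gives a
#'   modest, realistic spread so mean-variance trend fitting is well posed.
#' @param dispersion NB dispersion phi (variance = mu + phi * mu^2).
#' @param markers_per_cluster planted marker genes per cluster; marker sets
#'   are disjoint across clusters.
#' @param marker_fold mean multiplier (> 1) for a cluster's markers within
#'   that cluster.
#' @param mito_gene_fraction fraction of genes given the mitochondrial name
#'   prefix.
#' @param artifact_rates named list/vector with proportions `empty`,
#'   `high_mito`, `multiplet` (relative to the number of clean cells).
#' @param mito_prefix gene-name prefix marking mitochondrial genes
#'   (fly nomenclature default `"mt:"`).
#' @param n_replicates replicates per sex; cells are assigned uniformly.
#' @param seed integer seed; identical spec + seed give identical output.
#' @return A list of class `sim_count_spec`.
#' @export
sim_count_spec <- function(n_clusters = 5,
                           cells_per_cluster_per_sex = 50,
                           n_genes = 1000,
                           baseline_mean = 0.5,
                           gene_mean_sdlog = 0.5,
                           dispersion = 0.5,
                           markers_per_cluster = 40,
                           marker_fold = 4,
                           mito_gene_fraction = 0.02,
                           artifact_rates = c(empty = 0.02, high_mito = 0.02,
                                              multiplet = 0.02),
                           mito_prefix = "mt:",
                           n_replicates = 2,
                           seed = 1) {
  assert_scalar_num(n_clusters, "n_clusters", lower = 1, integer = TRUE)
  assert_scalar_num(n_genes, "n_genes", lower = 1, integer = TRUE)
  assert_scalar_num(baseline_mean, "baseline_mean", lower = 0, strict_lower = TRUE)
  assert_scalar_num(gene_mean_sdlog, "gene_mean_sdlog", lower = 0)
  assert_scalar_num(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  assert_scalar_num(markers_per_cluster, "markers_per_cluster", lower = 1,
                    integer = TRUE)
  assert_scalar_num(marker_fold, "marker_fold", lower = 1, strict_lower = TRUE)
  assert_proportion(mito_gene_fraction, "mito_gene_fraction")
  assert_scalar_num(n_replicates, "n_replicates", lower = 1, integer = TRUE)
  assert_scalar_num(seed, "seed", integer = TRUE)
  if (is.matrix(cells_per_cluster_per_sex)) {
    cc <- cells_per_cluster_per_sex
    if (nrow(cc) != n_clusters || ncol(cc) != 2)
      stop_field("cells_per_cluster_per_sex",
                 "matrix must be n_clusters x 2 (male, female)")
  } else {
    assert_scalar_num(cells_per_cluster_per_sex, "cells_per_cluster_per_sex",
                      lower = 0, integer = TRUE)
    cc <- matrix(cells_per_cluster_per_sex, n_clusters, 2)
  }
  colnames(cc) <- c("male", "female")
  if (any(cc < 0) || any(cc != round(cc)))
    stop_field("cells_per_cluster_per_sex", "entries must be non-negative integers")
  if (any(rowSums(cc) == 0))
    stop_field("cells_per_cluster_per_sex", "every cluster needs >= 1 cell")
  ar <- unlist(artifact_rates)
  for (nm in c("empty", "high_mito", "multiplet")) {
    if (is.na(ar[nm])) stop_field("artifact_rates", sprintf("missing rate '%s'", nm))
    assert_proportion(unname(ar[nm]), paste0("artifact_rates$", nm))
  }
  if (markers_per_cluster * n_clusters + ceiling(mito_gene_fraction * n_genes) >
      n_genes)
    stop_field("markers_per_cluster",
               "not enough genes for disjoint marker sets plus mito genes")
  structure(list(n_clusters = n_clusters, cells_per_cluster_per_sex = cc,
                 n_genes = n_genes, baseline_mean = baseline_mean,
                 gene_mean_sdlog = gene_mean_sdlog, dispersion = dispersion,
                 markers_per_cluster = markers_per_cluster,
                 marker_fold = marker_fold,
                 mito_gene_fraction = mito_gene_fraction,
                 artifact_rates = ar[c("empty", "high_mito", "multiplet")],
                 mito_prefix = mito_prefix, n_replicates = n_replicates,
                 seed = seed),
            class = "sim_count_spec")
}

# expected NB detection probability 1 - P(X = 0) for mean mu, dispersion phi
nb_detect_prob <- function(mu, phi) {
  size <- 1 / phi
  1 - (size / (size + mu))^size
}

#' Simulate a UMI count matrix with planted ground truth
#'
#' Draws negative-binomial counts per gene per cell.  Within a cluster the
#' planted marker genes have their mean multiplied by `marker_fold`.
#' Mitochondrial genes are ordinary genes carrying the mitochondrial name
#' prefix; in planted high-mito artifact cells their mean is inflated so the
#' mitochondrial UMI fraction is far above typical QC cutoffs.  Empty-droplet
#' artifacts are cells with all means scaled down until the expected number
#' of detected genes is ~100; multiplets are sums of two random clean cells.
#'
#' @param spec a [sim_count_spec].
#' @return A list with elements:
#'   * `cm`: a [fru_counts] containing clean cells followed by artifact cells;
#'   * `truth`: per-cell data.frame (barcode, cluster id or `NA` for
#'     artifacts, sex, replicate, artifact type);
#'   * `markers`: named list, planted marker gene ids per cluster;
#'   * `mito_genes`: mitochondrial gene ids.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_count_spec"))
  set.seed(spec$seed)
  n_mito <- ceiling(spec$mito_gene_fraction * spec$n_genes)
  n_reg <- spec$n_genes - n_mito
  gene_ids <- c(if (n_mito) paste0(spec$mito_prefix, "gene", seq_len(n_mito)),
                paste0("gene", seq_len(n_reg)))
  mito_genes <- gene_ids[seq_len(n_mito)]
  # disjoint marker blocks among non-mito genes
  markers <- vector("list", spec$n_clusters)
  names(markers) <- paste0("cluster", seq_len(spec$n_clusters) - 1L)
  pool <- gene_ids[(n_mito + 1L):spec$n_genes]
  for (k in seq_len(spec$n_clusters)) {
    take <- seq.int((k - 1L) * spec$markers_per_cluster + 1L,
                    k * spec$markers_per_cluster)
    markers[[k]] <- pool[take]
  }

  cc <- spec$cells_per_cluster_per_sex
  cluster_of <- rep(rep(seq_len(spec$n_clusters) - 1L, 2), times = c(cc))
  sex_of <- rep(rep(c("male", "female"), each = spec$n_clusters), times = c(cc))
  n_clean <- length(cluster_of)
  ord <- sample.int(n_clean)          # shuffle so cluster order is not positional
  cluster_of <- cluster_of[ord]; sex_of <- sex_of[ord]

  size <- 1 / spec$dispersion
  # per-gene baseline means: mean-corrected log-normal around baseline_mean
  sdl <- spec$gene_mean_sdlog
  base_mu <- spec$baseline_mean * exp(rnorm(spec$n_genes, -sdl^2 / 2, sdl))
  # planted markers sit at the typical expression level so their fold change
  # is detectable; only non-marker genes carry the abundance spread
  base_mu[match(unlist(markers), gene_ids)] <- spec$baseline_mean
  mu_mat <- matrix(base_mu, spec$n_genes, spec$n_clusters)
  for (k in seq_len(spec$n_clusters)) {
    idx <- match(markers[[k]], gene_ids)
    mu_mat[idx, k] <- mu_mat[idx, k] * spec$marker_fold
  }

  draw_cell <- function(mu) rnbinom(length(mu), mu = mu, size = size)
  clean <- vapply(seq_len(n_clean),
                  function(i) draw_cell(mu_mat[, cluster_of[i] + 1L]),
                  numeric(spec$n_genes))

  n_art <- round(spec$artifact_rates * n_clean)
  # empty droplets: scale all means so expected detected genes ~ 100
  target_detected <- min(100, 0.5 * spec$n_genes)
  f <- function(s) sum(nb_detect_prob(s * base_mu, spec$dispersion)) - target_detected
  empty_scale <- if (f(1) <= 0) 1 else stats::uniroot(f, c(1e-8, 1))$root
  empties <- if (n_art[["empty"]] > 0)
    vapply(seq_len(n_art[["empty"]]),
           function(i) draw_cell(empty_scale * base_mu),
           numeric(spec$n_genes)) else NULL
  # high-mito cells: a random cluster profile with mito means inflated so the
  # expected mito fraction is ~30% of UMIs
  himito <- NULL
  if (n_art[["high_mito"]] > 0 && n_mito > 0) {
    mito_tot <- sum(base_mu[seq_len(n_mito)])
    mito_boost <- (0.3 / 0.7) * (sum(base_mu) - mito_tot) / mito_tot
    himito <- vapply(seq_len(n_art[["high_mito"]]), function(i) {
      mu <- mu_mat[, sample.int(spec$n_clusters, 1L)]
      mu[seq_len(n_mito)] <- mu[seq_len(n_mito)] * mito_boost
      draw_cell(mu)
    }, numeric(spec$n_genes))
  }
  multi <- if (n_art[["multiplet"]] > 0 && n_clean >= 2)
    vapply(seq_len(n_art[["multiplet"]]), function(i) {
      pair <- sample.int(n_clean, 2L)
      clean[, pair[1L]] + clean[, pair[2L]]
    }, numeric(spec$n_genes)) else NULL

  art_type <- c(rep("empty", if (is.null(empties)) 0 else ncol(empties)),
                rep("high_mito", if (is.null(himito)) 0 else ncol(himito)),
                rep("multiplet", if (is.null(multi)) 0 else ncol(multi)))
  mat <- cbind(clean, empties, himito, multi)
  n_cells <- ncol(mat)
  barcodes <- sprintf("cell%05d", seq_len(n_cells))
  sex <- c(sex_of, sample(c("male", "female"), length(art_type), replace = TRUE))
  replicate <- paste0("rep", sample.int(spec$n_replicates, n_cells, replace = TRUE))
  truth <- data.frame(
    barcode = barcodes,
    cluster = c(cluster_of, rep(NA_integer_, length(art_type))),
    sex = sex, replicate = replicate,
    artifact = c(rep("none", n_clean), art_type),
    stringsAsFactors = FALSE)
  cm <- fru_counts(mat, gene_ids = gene_ids, barcodes = barcodes,
                   cell_meta = truth[, c("sex", "replicate")])
  list(cm = cm, truth = truth, markers = markers, mito_genes = mito_genes)
}

#' Specification for synthetic locomotor activity traces
#'
#' Describes per-fly 1-minute beam-crossing counts over several days: a
#' sinusoidally modulated Poisson process at a planted free-running period,
#' optional planted sleep blocks (runs of zero minutes), and a fraction of
#' flies that die early in the recording.
#'
#' @param n_flies number of flies.
#' @param n_days recording length in days (trace length `n_days * 1440`).
#' @param period_h planted period in hours, within `[18, 30]`.
#' @param amplitude relative modulation depth (0 = stationary activity).
#' @param baseline_rate Poisson mean counts per minute for live flies.
#' @param dead_fly_fraction fraction of flies (rounded) that die during day 1;
#'   after death their counts are all zero, so at least one full day is below
#'   any sensible dead-fly threshold.
#' @param sleep_block_minutes length of a planted zero-activity block inserted
#'   once per day per live fly (0 disables).
#' @param lights_on,lights_off schedule, minutes after midnight.
#' @param seed integer seed.
#' @return A list of class `sim_activity_spec`.
#' @export
sim_activity_spec <- function(n_flies = 16, n_days = 10, period_h = 24,
                              amplitude = 1, baseline_rate = 2,
                              dead_fly_fraction = 0, sleep_block_minutes = 0,
                              lights_on = 480, lights_off = 1200, seed = 1) {
  assert_scalar_num(n_flies, "n_flies", lower = 1, integer = TRUE)
  assert_scalar_num(n_days, "n_days", lower = 1, integer = TRUE)
  assert_scalar_num(period_h, "period_h", lower = 18, upper = 30)
  assert_scalar_num(amplitude, "amplitude", lower = 0)
  assert_scalar_num(baseline_rate, "baseline_rate", lower = 0)
  assert_proportion(dead_fly_fraction, "dead_fly_fraction")
  assert_scalar_num(sleep_block_minutes, "sleep_block_minutes", lower = 0,
                    integer = TRUE)
  assert_scalar_num(seed, "seed", integer = TRUE)
  structure(list(n_flies = n_flies, n_days = n_days, period_h = period_h,
                 amplitude = amplitude, baseline_rate = baseline_rate,
                 dead_fly_fraction = dead_fly_fraction,
                 sleep_block_minutes = sleep_block_minutes,
                 lights_on = lights_on, lights_off = lights_off, seed = seed),
            class = "sim_activity_spec")
}

#' Simulate per-fly minute-binned activity traces
#'
#' @param spec a [sim_activity_spec].
#' @param genotype,sex labels attached to every generated trace.
#' @return A list of `activity_trace` objects (see [activity_trace]); dead
#'   flies come last and are recorded in the `dead` attribute.
#' @export
simulate_activity <- function(spec, genotype = "sim", sex = "male") {
  stopifnot(inherits(spec, "sim_activity_spec"))
  set.seed(spec$seed)
  n_min <- spec$n_days * 1440L
  t_min <- seq_len(n_min) - 1L
  modulation <- 1 + spec$amplitude * sin(2 * pi * t_min / (spec$period_h * 60))
  rate <- pmax(0, spec$baseline_rate * modulation)
  n_dead <- round(spec$dead_fly_fraction * spec$n_flies)
  dead_ids <- if (n_dead > 0)
    sprintf("fly%02d", spec$n_flies - n_dead + seq_len(n_dead)) else character()
  traces <- lapply(seq_len(spec$n_flies), function(i) {
    id <- sprintf("fly%02d", i)
    counts <- rpois(n_min, rate)
    if (id %in% dead_ids) {
      death <- sample.int(720, 1L)      # dies during the first half-day
      counts[seq.int(death, n_min)] <- 0L
    } else if (spec$sleep_block_minutes > 0) {
      for (d in seq_len(spec$n_days)) {
        start <- (d - 1L) * 1440L + sample.int(1440L - spec$sleep_block_minutes, 1L)
        counts[seq.int(start, start + spec$sleep_block_minutes - 1L)] <- 0L
      }
    }
    activity_trace(id, counts, lights_on = spec$lights_on,
                   lights_off = spec$lights_off, genotype = genotype, sex = sex)
  })
  names(traces) <- vapply(traces, function(tr) tr$fly_id, character(1))
  attr(traces, "dead") <- dead_ids
  traces
}
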