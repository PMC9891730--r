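#' Default pipeline configuration
#'
#' Assembles every stage parameter (with the standard defaults) into one
#' list; any element can be overridden through `...`.  Inputs are given
#' either as 10x triplet paths (`matrix_path`, `genes_path`,
#' `barcodes_path`, `meta_path`) or as an in-memory [fru_counts] via the
#' `cm` argument of [run_pipeline()].
#'
#' @param ... overrides for any default element.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    matrix_path = NULL, genes_path = NULL, barcodes_path = NULL,
    meta_path = NULL,
    mito_prefix = "mt:",
    qc = qc_thresholds(),
    neuron_genes = c("elav", "nSyb", "noe"),
    scale_factor = 1e4,
    n_hvg = 2000,
    max_pcs = 20,
    jackstraw_reps = 100, jackstraw_prop = 0.01, jackstraw_alpha = 0.05,
    min_pcs = 2,
    k_neighbors = 20, resolution = 0.8,
    marker_min_pct = 0.25, marker_logfc = 0.25, marker_alpha = 0.05,
    fold_biased = 2, fold_strong = 4,
    rules = annotation_rules(), rules_path = NULL,
    hox_genes = c("Antp", "Ubx", "abd-A", "Abd-B"),
    fan_trio = c("VAChT", "Gad1", "VGlut"),
    robustness_runs = 0, robustness_seed_base = 100,
    match_cutoff = 0.5,
    subcluster_specs = list(),
    run_umap = FALSE,
    seed = 1,
    out_dir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_field("config", sprintf("unknown option(s): %s",
                                 paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  if (!is.null(cfg$rules_path)) cfg$rules <- read_annotation_rules(cfg$rules_path)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  paths <- c(cfg$matrix_path, cfg$genes_path, cfg$barcodes_path,
             cfg$meta_path, cfg$rules_path)
  for (p in paths)
    if (!is.null(p) && !file.exists(p))
      stop_field("config", sprintf("referenced file does not exist: %s", p))
  invisible(cfg)
}

#' Run the full single-cell pipeline
#'
#' Stages run in order: QC filtering -> neuron classification ->
#' normalization -> HVG selection -> PCA with jackstraw PC selection ->
#' SNN clustering (-> UMAP) -> markers -> within-cluster sex DE -> sex-bias
#' classification -> annotation -> Hox correlations and FAN overlap ->
#' optional downsampling robustness runs -> optional subclustering.  A
#' manifest of every parameter and seed is attached, and stage tables are
#' written as TSV/JSON when `out_dir` is set.  Re-running with an identical
#' config and input reproduces every deterministic output bit-for-bit.
#'
#' @param config a [pipeline_config].
#' @param cm optional in-memory [fru_counts] (otherwise loaded from the
#'   configured triplet paths).
#' @return A list of class `fru_pipeline` with elements `qc`, `neurons`,
#'   `cm` (filtered cells), `nm`, `hvgs`, `pca`, `clusters`, `umap`,
#'   `markers`, `sex_de`, `sex_bias`, `annotation`, `hox_correlation`,
#'   `fan_overlap`, `robustness`, `subclusters`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cm = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  state <- list(manifest = list(params = unclass(config),
                                started = format(Sys.time())))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (is.null(cm))
    cm <- stage("load", load_counts(config$matrix_path, config$genes_path,
                                    config$barcodes_path, config$meta_path))
  filt <- stage("qc", filter_cells(cm, config$qc,
                                   mito_prefix = config$mito_prefix))
  state$qc <- filt$qc
  state$cm <- filt$cm
  state$neurons <- stage("neurons",
                         suppressWarnings(classify_neurons(state$cm,
                                                           config$neuron_genes)))
  state$nm <- stage("normalize", log_normalize(state$cm, config$scale_factor))
  state$hvgs <- stage("hvg",
                      suppressWarnings(select_hvgs(state$cm, config$n_hvg)))
  state$pca <- stage("pca", suppressWarnings(jackstraw_select_pcs(
    state$nm, state$hvgs,
    max_pcs = min(config$max_pcs, min(dim(state$nm)) - 1L),
    prop = config$jackstraw_prop, n_reps = config$jackstraw_reps,
    alpha = config$jackstraw_alpha, seed = config$seed,
    min_pcs = config$min_pcs)))
  state$clusters <- stage("cluster", cluster_snn(
    state$pca, k = config$k_neighbors, resolution = config$resolution,
    seed = config$seed))
  if (isTRUE(config$run_umap))
    state$umap <- stage("umap", umap_embed(state$pca, seed = config$seed))
  state$markers <- stage("markers", suppressWarnings(find_markers(
    state$cm, state$nm, state$clusters, min_pct = config$marker_min_pct,
    logfc_threshold = config$marker_logfc, alpha = config$marker_alpha)))
  state$sex_de <- stage("sex_de", suppressWarnings(find_sex_de_within_cluster(
    state$cm, state$nm, state$clusters, min_pct = config$marker_min_pct,
    logfc_threshold = config$marker_logfc, alpha = config$marker_alpha)))
  state$scaling_factor <- stage("sexbias", compute_scaling(state$cm))
  state$sex_bias <- stage("sexbias", classify_clusters(
    cluster_sex_counts(state$clusters, state$cm), state$scaling_factor,
    fold_biased = config$fold_biased, fold_strong = config$fold_strong))
  state$sex_de_summary <- summarize_sex_de(state$sex_de)
  pct <- stage("annotate", cluster_pct_expressed(
    state$cm, state$clusters, genes = unique(unlist(config$rules))))
  state$annotation <- stage("annotate", annotate_clusters(
    state$markers, config$rules, pct_expressed = pct))
  hox_present <- intersect(config$hox_genes, rownames(state$nm))
  if (length(hox_present) >= 2)
    state$hox_correlation <- stage("coexpr", suppressWarnings(
      pairwise_correlation(state$nm, hox_present)))
  if (all(config$fan_trio %in% state$cm$gene_ids))
    state$fan_overlap <- stage("coexpr", suppressWarnings(
      overlap_proportions(state$cm, config$fan_trio)))

  if (config$robustness_runs > 0)
    state$robustness <- stage("robustness",
                              run_robustness(state, config))
  if (length(config$subcluster_specs))
    state$subclusters <- stage("subcluster", lapply(
      config$subcluster_specs, function(sp)
        subset_and_recluster(state$cm, state$nm, state$clusters, sp)))

  state$manifest$finished <- format(Sys.time())
  state$manifest$n_cells_in <- ncol(cm$counts)
  state$manifest$n_cells_kept <- ncol(state$cm$counts)
  state$manifest$n_clusters <- length(unique(state$clusters$labels))
  class(state) <- "fru_pipeline"
  if (!is.null(config$out_dir)) write_pipeline_outputs(state, config$out_dir)
  state
}

run_robustness <- function(state, config) {
  sex <- state$cm$cell_meta$sex
  target <- min(sum(sex == "male"), sum(sex == "female"))
  ref_prof <- cluster_profiles(state$nm, state$clusters, state$hvgs)
  runs <- lapply(seq_len(config$robustness_runs), function(i) {
    seed_i <- config$robustness_seed_base + i
    sub <- downsample(state$cm, target, seed = seed_i)
    sub_nm <- log_normalize(sub, config$scale_factor)
    sub_hvgs <- suppressWarnings(select_hvgs(sub, config$n_hvg))
    sub_pca <- suppressWarnings(jackstraw_select_pcs(
      sub_nm, sub_hvgs, max_pcs = min(config$max_pcs, min(dim(sub_nm)) - 1L),
      prop = config$jackstraw_prop, n_reps = config$jackstraw_reps,
      alpha = config$jackstraw_alpha, seed = seed_i,
      min_pcs = config$min_pcs))
    sub_cl <- cluster_snn(sub_pca, k = config$k_neighbors,
                          resolution = config$resolution, seed = seed_i)
    prof <- cluster_profiles(sub_nm, sub_cl, state$hvgs)
    match <- match_clusters(ref_prof, prof, cutoff = config$match_cutoff)
    report <- classify_clusters(cluster_sex_counts(sub_cl, sub),
                                compute_scaling(sub),
                                fold_biased = config$fold_biased,
                                fold_strong = config$fold_strong)
    list(seed = seed_i, kept_barcodes = sub$barcodes, match = match,
         report = report)
  })
  list(runs = runs,
       concordance = concordance_report(state$sex_bias, runs))
}

write_pipeline_outputs <- function(state, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(state$qc, "qc_report.tsv")
  tsv(data.frame(barcode = names(state$clusters$labels),
                 cluster = state$clusters$labels), "clusters.tsv")
  tsv(as.data.frame(state$markers), "markers.tsv")
  tsv(as.data.frame(state$sex_de), "sex_de.tsv")
  tsv(as.data.frame(state$sex_bias), "sex_bias.tsv")
  tsv(state$annotation, "annotation.tsv")
  if (!is.null(state$umap))
    tsv(data.frame(barcode = rownames(state$umap), state$umap), "umap.tsv")
  manifest <- state$manifest
  manifest$params$qc <- unclass(manifest$params$qc)
  manifest$params$rules <- unclass(manifest$params$rules)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE)
  invisible(out_dir)
}
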