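#' Default marker-gene annotation rule set
#'
#' Named gene lists driving the declarative cluster-annotation rules:
#' Hox segment-identity genes for ventral nerve cord (VNC) clusters, mushroom
#' body Kenyon cell (KC) genes, fast-acting neurotransmitter (FAN) genes,
#' aminergic pathway genes, core circadian clock genes, and configurable
#' neuropeptide / receptor vocabularies.
#'
#' @param neuropeptides,receptors optional extra gene vocabularies.
#' @return A named list of character vectors of class `annotation_rules`.
#' @export
annotation_rules <- function(neuropeptides = character(),
                             receptors = character()) {
  rules <- list(
    hox = c("Antp", "Ubx", "abd-A", "Abd-B"),
    kc_core = c("ey", "Dop1R2"),
    kc_axon = c("sNPF", "Fas2"),
    kc_gamma = "trio",
    cholinergic = c("VAChT", "ChAT"),
    gabaergic = c("Gad1", "VGAT"),
    glutamatergic = "VGlut",
    aminergic = "Vmat",
    dopaminergic = c("DAT", "ple"),
    serotonergic = "SerT",
    tyr_oct = "Tdc2",
    circadian = c("per", "tim", "Clk", "vri", "Pdp1"),
    neuropeptides = as.character(neuropeptides),
    receptors = as.character(receptors))
  structure(rules, class = "annotation_rules")
}

#' Read an annotation rule set from a JSON config
#'
#' @param path JSON file mapping rule names to gene arrays; unnamed rules
#'   fall back to the defaults of [annotation_rules()].
#' @return An `annotation_rules` list.
#' @export
read_annotation_rules <- function(path) {
  if (!file.exists(path)) stop_field("path", sprintf("file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- annotation_rules()
  for (nm in names(cfg)) rules[[nm]] <- as.character(cfg[[nm]])
  structure(rules, class = "annotation_rules")
}

#' Annotate clusters with the declarative marker-gene rules
#'
#' Applies boolean rules over each cluster's marker-gene set (and, for the
#' low-confidence KC rule, over genes expressed in the cluster at a minimum
#' detection fraction without being markers):
#' * `VNC`: at least one Hox marker gene;
#' * `KC_ab` (high confidence): >= 1 KC core marker (ey/Dop1R2) and >= 1 KC
#'   axon marker (sNPF/Fas2), with trio *not* a marker;
#' * `KC_gamma` (high confidence): the same plus trio as a marker;
#' * `KC` (low confidence): both KC axon genes are markers and >= 1 KC core
#'   gene is expressed-but-not-a-marker, or trio is a marker together with
#'   exactly one other KC gene from Fas2/Dop1R2;
#' * `cholinergic` / `gabaergic` / `glutamatergic`: >= 1 respective marker
#'   (multi-label allowed);
#' * `dopaminergic` (DAT and/or ple), `serotonergic` (SerT), `tyr_oct`
#'   (Tdc2), `aminergic` (Vmat);
#' * `circadian`: >= 2 clock genes as markers;
#' * `neuropeptide` / `receptor`: >= 1 list member as marker.
#'
#' The engine is pure: a cluster's labels depend only on its own marker and
#' detection columns.
#'
#' @param marker_table a `marker_table` from [find_markers()].
#' @param rules an `annotation_rules` list.
#' @param pct_expressed optional genes x clusters matrix (or data.frame) of
#'   within-cluster detection fractions, required only for the
#'   low-confidence KC rule; see [cluster_pct_expressed()].
#' @param expressed_min detection fraction at which a non-marker gene counts
#'   as "expressed in the cluster" (default 0.25).
#' @param clusters clusters to annotate (default: all in the marker table).
#' @return data.frame `cluster`, `label`, `confidence` (`high`/`low`),
#'   `supporting_genes` (comma-separated).
#' @export
annotate_clusters <- function(marker_table, rules = annotation_rules(),
                              pct_expressed = NULL, expressed_min = 0.25,
                              clusters = NULL) {
  stopifnot(inherits(rules, "annotation_rules"))
  clusters <- clusters %||% sort(unique(marker_table$cluster))
  res <- lapply(clusters, function(cl) {
    mk <- marker_table$gene[marker_table$cluster == cl]
    expressed <- if (!is.null(pct_expressed)) {
      pc <- pct_expressed[, as.character(cl)]
      rownames(pct_expressed)[pc >= expressed_min]
    } else character()
    annotate_one_cluster(cl, mk, expressed, rules)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(cluster = integer(), label = character(),
                      confidence = character(), supporting_genes = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

annotate_one_cluster <- function(cl, markers, expressed, rules) {
  hits <- function(set) intersect(rules[[set]], markers)
  lab <- list()
  add <- function(label, confidence, genes) {
    lab[[length(lab) + 1L]] <<- data.frame(
      cluster = cl, label = label, confidence = confidence,
      supporting_genes = paste(genes, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(h <- hits("hox"))) add("VNC", "high", h)

  core <- hits("kc_core"); axon <- hits("kc_axon"); gamma <- hits("kc_gamma")
  if (length(core) && length(axon)) {
    if (length(gamma)) add("KC_gamma", "high", c(core, axon, gamma))
    else add("KC_ab", "high", c(core, axon))
  } else {
    core_expr <- intersect(rules$kc_core, setdiff(expressed, markers))
    low_a <- setequal(intersect(rules$kc_axon, markers), rules$kc_axon) &&
      length(core_expr) > 0
    other_kc <- intersect(c("Fas2", "Dop1R2"), markers)
    low_b <- length(gamma) > 0 && length(other_kc) == 1
    if (low_a) add("KC", "low", c(intersect(rules$kc_axon, markers), core_expr))
    else if (low_b) add("KC", "low", c(gamma, other_kc))
  }

  for (fan in c("cholinergic", "gabaergic", "glutamatergic"))
    if (length(h <- hits(fan))) add(fan, "high", h)
  if (length(h <- hits("dopaminergic"))) add("dopaminergic", "high", h)
  if (length(h <- hits("serotonergic"))) add("serotonergic", "high", h)
  if (length(h <- hits("tyr_oct"))) add("tyr_oct", "high", h)
  if (length(h <- hits("aminergic"))) add("aminergic", "high", h)
  if (length(h <- hits("circadian")) >= 2) add("circadian", "high", h)
  if (length(h <- hits("neuropeptides"))) add("neuropeptide", "high", h)
  if (length(h <- hits("receptors"))) add("receptor", "high", h)
  if (length(lab)) do.call(rbind, lab) else NULL
}

#' Within-cluster detection fractions
#'
#' @param cm a [fru_counts].
#' @param labels per-cell cluster labels.
#' @param genes genes to tabulate (default all).
#' @return genes x clusters matrix of fractions of cells with UMIs > 0.
#' @export
cluster_pct_expressed <- function(cm, labels, genes = NULL) {
  labels <- label_vector(labels, cm)
  genes <- genes %||% cm$gene_ids
  genes <- intersect(genes, cm$gene_ids)
  cls <- sort(unique(labels))
  if (!length(genes))
    return(matrix(numeric(0), 0, length(cls),
                  dimnames = list(character(0), as.character(cls))))
  out <- vapply(cls, function(cl)
    Matrix::rowMeans(cm$counts[genes, labels == cl, drop = FALSE] > 0),
    numeric(length(genes)))
  matrix(out, nrow = length(genes),
         dimnames = list(genes, as.character(cls)))
}

#' Flag cells expressing any member of each gene set
#'
#' @param cm a [fru_counts].
#' @param gene_sets named list of gene-id vectors; unknown genes warn and are
#'   ignored.
#' @return A list: `flags` (cells x sets logical matrix; a flag is TRUE iff
#'   any member gene has UMIs > 0) and `fraction_by_sex` (sets x sex matrix
#'   of flag fractions).
#' @export
classify_cells_by_sets <- function(cm, gene_sets) {
  stopifnot(inherits(cm, "fru_counts"), is.list(gene_sets))
  flags <- vapply(gene_sets, function(genes) {
    missing <- setdiff(genes, cm$gene_ids)
    if (length(missing))
      warning(sprintf("gene(s) not in matrix: %s",
                      paste(missing, collapse = ", ")))
    genes <- intersect(genes, cm$gene_ids)
    if (!length(genes)) return(rep(FALSE, ncol(cm$counts)))
    as.logical(Matrix::colSums(cm$counts[genes, , drop = FALSE] > 0) > 0)
  }, logical(ncol(cm$counts)))
  rownames(flags) <- cm$barcodes
  sex <- cm$cell_meta$sex
  frac <- t(vapply(colnames(flags), function(s)
    c(male = mean(flags[sex == "male", s]),
      female = mean(flags[sex == "female", s])), numeric(2)))
  list(flags = flags, fraction_by_sex = frac)
}

#' Serotonergic neurons with posterior Hox expression
#'
#' Selects cells with SerT UMIs > 0 and abd-A and/or Abd-B UMIs > 0 -- the
#' expression signature of serotonergic neurons of the abdominal ganglion of
#' the ventral nerve cord.
#'
#' @param cm a [fru_counts].
#' @param sert,hox gene ids used for the predicate.
#' @return A list: `barcodes` of qualifying cells, and `counts_by_sex`
#'   (named integer vector, male/female).
#' @export
select_serotonergic_vnc <- function(cm, sert = "SerT",
                                    hox = c("abd-A", "Abd-B")) {
  stopifnot(inherits(cm, "fru_counts"))
  need <- c(sert, hox)
  missing <- setdiff(need, cm$gene_ids)
  if (length(missing))
    stop_field("cm", sprintf("gene(s) not in matrix: %s",
                             paste(missing, collapse = ", ")))
  sert_pos <- cm$counts[sert, ] > 0
  hox_pos <- Matrix::colSums(cm$counts[hox, , drop = FALSE] > 0) > 0
  sel <- as.logical(sert_pos & hox_pos)
  sex <- cm$cell_meta$sex[sel]
  list(barcodes = cm$barcodes[sel],
       counts_by_sex = c(male = sum(sex == "male"),
                         female = sum(sex == "female")))
}
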