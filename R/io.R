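#' Read a 10x-style triplet count matrix with cell metadata
#'
#' Reads a Matrix Market sparse matrix plus `genes.tsv` and `barcodes.tsv`
#' files, and a per-cell metadata TSV with columns `barcode`, `sex`,
#' `replicate`.  Duplicate gene ids are disambiguated deterministically by
#' appending `.1`, `.2`, ... to later occurrences.
#'
#' @param matrix_path path to the `.mtx` file (genes x cells).
#' @param genes_path path to a headerless TSV whose first column is gene ids.
#' @param barcodes_path path to a headerless TSV of barcodes.
#' @param meta_path path to a TSV (with header) of per-cell metadata.
#' @return A [fru_counts] object.
#' @export
load_counts <- function(matrix_path, genes_path, barcodes_path, meta_path) {
  for (p in c(matrix_path, genes_path, barcodes_path, meta_path))
    if (!file.exists(p)) stop_field("path", sprintf("file not found: %s", p))
  m <- Matrix::readMM(matrix_path)
  genes <- read.delim(genes_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(barcodes_path, header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (length(genes) != nrow(m))
    stop_field("genes_path", sprintf("%d gene ids but matrix has %d rows",
                                     length(genes), nrow(m)))
  if (length(barcodes) != ncol(m))
    stop_field("barcodes_path", sprintf(
      "%d barcodes but matrix has %d columns", length(barcodes), ncol(m)))
  genes <- make.unique(genes, sep = ".")
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (is.null(meta$barcode)) stop_field("meta_path", "missing 'barcode' column")
  idx <- match(barcodes, meta$barcode)
  if (anyNA(idx))
    stop_field("meta_path", sprintf("no metadata for barcode %s",
                                    barcodes[which(is.na(idx))[1L]]))
  fru_counts(m, gene_ids = genes, barcodes = barcodes,
             cell_meta = meta[idx, , drop = FALSE])
}

#' Write a count matrix as a 10x-style triplet plus metadata TSV
#'
#' @param cm a [fru_counts].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (matrix, genes, barcodes, meta).
#' @export
write_counts_10x <- function(cm, dir) {
  stopifnot(inherits(cm, "fru_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                            "cell_meta.tsv"))
  Matrix::writeMM(cm$counts, paths[1])
  write.table(data.frame(cm$gene_ids), paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(cm$barcodes), paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(cm$cell_meta, paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(setNames(paths, c("matrix", "genes", "barcodes", "meta")))
}

#' Write activity traces as long-format CSV plus a schedule JSON
#'
#' @param traces list of `activity_trace` objects.
#' @param csv_path output CSV (`fly_id`, `minute_index`, `counts`; one extra
#'   column each for `genotype` and `sex`).
#' @param schedule_path output JSON with `lights_on`/`lights_off`
#'   (minutes after midnight).
#' @return Invisibly the CSV path.
#' @export
write_activity_csv <- function(traces, csv_path, schedule_path = NULL) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(fly_id = tr$fly_id, minute_index = seq_along(tr$counts) - 1L,
               counts = tr$counts, genotype = tr$genotype, sex = tr$sex,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(schedule_path)) {
    sch <- traces[[1]]$schedule
    jsonlite::write_json(list(lights_on = sch$lights_on,
                              lights_off = sch$lights_off),
                         schedule_path, auto_unbox = TRUE)
  }
  invisible(csv_path)
}

#' Read activity traces from CSV (plus optional schedule JSON)
#'
#' @param csv_path CSV as written by [write_activity_csv()].
#' @param schedule_path optional JSON with `lights_on`/`lights_off`; defaults
#'   to lights on 08:00, off 20:00.
#' @return A named list of `activity_trace` objects.
#' @export
read_activity_csv <- function(csv_path, schedule_path = NULL) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  sch <- if (!is.null(schedule_path)) jsonlite::read_json(schedule_path)
         else list(lights_on = 480, lights_off = 1200)
  traces <- lapply(split(df, df$fly_id), function(d) {
    d <- d[order(d$minute_index), ]
    activity_trace(d$fly_id[1], d$counts,
                   lights_on = sch$lights_on, lights_off = sch$lights_off,
                   genotype = if (!is.null(d$genotype)) d$genotype[1] else NA,
                   sex = if (!is.null(d$sex)) d$sex[1] else NA)
  })
  traces[order(names(traces))]
}

#' Read a tab-separated activity-monitor file
#'
#' Permissive reader for Trikinetics-style monitor text: tab-separated rows
#' whose last 32 columns are the per-channel beam-cross counts for one
#' minute, preceded by index/timestamp/status columns.  Channels become flies
#' `<prefix>01` ... `<prefix>32`.
#'
#' @param path monitor file path.
#' @param lights_on,lights_off schedule, minutes after midnight.
#' @param prefix fly-id prefix (default the file base name plus `_ch`).
#' @param genotype,sex labels attached to every trace.
#' @return A named list of `activity_trace` objects (channels with any
#'   non-integer data are dropped with a warning).
#' @export
read_dam_monitor <- function(path, lights_on = 480, lights_off = 1200,
                             prefix = NULL, genotype = NA, sex = NA) {
  if (!file.exists(path)) stop_field("path", sprintf("file not found: %s", path))
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 33)
    stop_field("path", "monitor file needs >= 33 tab-separated columns")
  counts <- raw[, (ncol(raw) - 31L):ncol(raw), drop = FALSE]
  prefix <- prefix %||% paste0(sub("\\.[^.]*$", "", basename(path)), "_ch")
  traces <- lapply(seq_len(32L), function(ch) {
    x <- suppressWarnings(as.numeric(counts[[ch]]))
    if (anyNA(x) || any(x < 0) || any(x != round(x))) return(NULL)
    activity_trace(sprintf("%s%02d", prefix, ch), as.integer(x),
                   lights_on = lights_on, lights_off = lights_off,
                   genotype = genotype, sex = sex, pad = TRUE)
  })
  drop <- vapply(traces, is.null, logical(1))
  if (any(drop))
    warning(sprintf("dropped %d channel(s) with non-count data", sum(drop)))
  traces <- traces[!drop]
  names(traces) <- vapply(traces, function(tr) tr$fly_id, character(1))
  traces
}
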