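#' Female-to-male scaling factor
#'
#' Ratio of total female to total male cells; used to normalize per-cluster
#' female cell counts when the data set contains unequal numbers of cells
#' from the two sexes.
#'
#' @param cm a [fru_counts], or a per-cell sex vector.
#' @return Positive scalar `s = n_female / n_male`.
#' @export
compute_scaling <- function(cm) {
  sex <- if (inherits(cm, "fru_counts")) cm$cell_meta$sex else as.character(cm)
  n_m <- sum(sex == "male")
  n_f <- sum(sex == "female")
  if (n_m == 0) stop_field("cm", "no male cells; scaling factor undefined")
  if (n_f == 0) stop_field("cm", "no female cells; scaling factor undefined")
  n_f / n_m
}

#' Classify clusters by sex composition
#'
#' Female counts are divided by the scaling factor `s`; a cluster is
#' *sex-specific* when the other sex contributes zero raw cells (specificity
#' is decided on raw counts - a zero is a zero regardless of scaling),
#' *sex-biased, strong* when the normalized count ratio strictly exceeds
#' `fold_strong`, *sex-biased* when it strictly exceeds `fold_biased`, and
#' unbiased otherwise.  Classes are mutually exclusive with specificity
#' taking precedence.
#'
#' @param counts per-cluster sex counts: a data.frame with columns `cluster`,
#'   `n_male`, `n_female`, or the result of [cluster_sex_counts()].
#' @param s scaling factor from [compute_scaling()].
#' @param fold_biased,fold_strong strict ratio thresholds (defaults 2 and 4).
#' @return A data.frame of class `sex_bias_report`: `cluster`, `n_male`,
#'   `n_female_raw`, `n_female_norm`, `ratio` (larger/smaller of male vs
#'   normalized female, `Inf` for specific clusters), `class` in
#'   `male_specific`, `female_specific`, `male_biased_strong`,
#'   `female_biased_strong`, `male_biased`, `female_biased`, `unbiased`.
#'   Class tallies and percentages are in the `summary` attribute.
#' @export
classify_clusters <- function(counts, s, fold_biased = 2, fold_strong = 4) {
  assert_scalar_num(s, "s", lower = 0, strict_lower = TRUE)
  assert_scalar_num(fold_biased, "fold_biased", lower = 1)
  assert_scalar_num(fold_strong, "fold_strong", lower = fold_biased)
  stopifnot(all(c("cluster", "n_male", "n_female") %in% names(counts)))
  n_m <- counts$n_male
  n_f <- counts$n_female
  if (any(n_m < 0) || any(n_f < 0))
    stop_field("counts", "cell counts must be non-negative")
  empty <- n_m == 0 & n_f == 0
  if (any(empty)) {
    warning(sprintf("%d empty cluster(s) excluded", sum(empty)))
    counts <- counts[!empty, , drop = FALSE]
    n_m <- counts$n_male; n_f <- counts$n_female
  }
  n_f_norm <- n_f / s
  ratio <- pmax(n_m, n_f_norm) / pmin(n_m, n_f_norm)   # Inf when one side 0
  cls <- rep("unbiased", nrow(counts))
  male_larger <- n_m > n_f_norm
  cls[male_larger & ratio > fold_biased] <- "male_biased"
  cls[!male_larger & ratio > fold_biased] <- "female_biased"
  cls[male_larger & ratio > fold_strong] <- "male_biased_strong"
  cls[!male_larger & ratio > fold_strong] <- "female_biased_strong"
  cls[n_f == 0 & n_m > 0] <- "male_specific"
  cls[n_m == 0 & n_f > 0] <- "female_specific"
  out <- data.frame(cluster = counts$cluster, n_male = n_m,
                    n_female_raw = n_f, n_female_norm = n_f_norm,
                    ratio = ratio, class = cls, stringsAsFactors = FALSE)
  lv <- c("male_specific", "female_specific", "male_biased_strong",
          "female_biased_strong", "male_biased", "female_biased", "unbiased")
  tally <- table(factor(cls, levels = lv))
  attr(out, "summary") <- list(
    scaling_factor = s, n_clusters = nrow(out),
    tally = as.list(tally),
    percent = as.list(round(100 * as.numeric(tally) / nrow(out), 2)) |>
      setNames(lv))
  class(out) <- c("sex_bias_report", class(out))
  out
}

#' Per-cluster sex counts
#'
#' @param labels per-cell cluster labels (vector or `fru_clusters`).
#' @param sex per-cell sex labels, or a [fru_counts] whose metadata supplies
#'   them.
#' @return data.frame with `cluster`, `n_male`, `n_female`.
#' @export
cluster_sex_counts <- function(labels, sex) {
  if (inherits(labels, "fru_clusters")) labels <- labels$labels
  if (inherits(sex, "fru_counts")) sex <- sex$cell_meta$sex
  stopifnot(length(labels) == length(sex))
  tab <- table(cluster = labels, sex = factor(sex, c("male", "female")))
  data.frame(cluster = rownames(tab),
             n_male = as.integer(tab[, "male"]),
             n_female = as.integer(tab[, "female"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate within-cluster sex-DE results into uniquely biased gene sets
#'
#' @param sex_de result of [find_sex_de_within_cluster()] (needs `gene` and
#'   `direction` columns).
#' @return A list with disjoint character vectors `uniquely_male`,
#'   `uniquely_female` and `mixed`, whose union is every gene sex-biased in
#'   at least one cluster.
#' @export
summarize_sex_de <- function(sex_de) {
  male_genes <- unique(sex_de$gene[sex_de$direction == "male"])
  female_genes <- unique(sex_de$gene[sex_de$direction == "female"])
  list(uniquely_male = sort(setdiff(male_genes, female_genes)),
       uniquely_female = sort(setdiff(female_genes, male_genes)),
       mixed = sort(intersect(male_genes, female_genes)))
}
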