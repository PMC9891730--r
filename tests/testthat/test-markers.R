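test_that("rank-sum p-values from the marker test match exact enumeration", {
  # hand case: cluster values {3,4} vs rest {1,2} -> two-sided p = 1/3
  cm <- two_group_counts(c(3, 4, 1, 2), labels = c(0, 0, 1, 1))
  nm <- log_normalize(cm)
  tab <- find_markers(cm, nm, c(0, 0, 1, 1), min_pct = 0, logfc_threshold = 0,
                      alpha = 1.01, min_cells = 2)
  g <- tab[tab$cluster == 0 & tab$gene == "g", ]
  expect_equal(g$p_raw, 1 / 3, tolerance = 1e-12)
  # parameterized: random no-tie group values, sizes <= 8
  set.seed(10)
  for (i in 1:12) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    vals <- sample(seq(2, 80, by = 2), n1 + n2)   # distinct, even
    vals[seq_len(n1)] <- vals[seq_len(n1)] + 41   # enrich group 1 (odd offset: no cross-group ties)
    labels <- rep(c(0, 1), c(n1, n2))
    cm <- two_group_counts(vals, labels, total = max(vals) + 3)
    nm <- log_normalize(cm)
    tab <- find_markers(cm, nm, labels, min_pct = 0, logfc_threshold = 0,
                        alpha = 1.01, min_cells = 2)
    row <- tab[tab$gene == "g", ][1, ]   # two-sided p is direction-symmetric
    expect_equal(row$p_raw,
                 exact_ranksum_p(vals[seq_len(n1)], vals[-seq_len(n1)]),
                 tolerance = 1e-10)
  }
})

test_that("tied data follow the tie-corrected normal approximation", {
  set.seed(20)
  for (i in 1:8) {
    n1 <- sample(9:15, 1); n2 <- sample(9:15, 1)
    vals <- sample(0:6, n1 + n2, replace = TRUE)
    vals[seq_len(n1)] <- vals[seq_len(n1)] + 3
    labels <- rep(c(0, 1), c(n1, n2))
    cm <- two_group_counts(vals, labels, total = max(vals) + 3)
    nm <- log_normalize(cm)
    tab <- find_markers(cm, nm, labels, min_pct = 0, logfc_threshold = 0,
                        alpha = 1.01, min_cells = 2)
    row <- tab[tab$gene == "g", ][1, ]
    if (!is.na(row$p_raw))
      expect_equal(row$p_raw,
                   normal_ranksum_p(vals[seq_len(n1)], vals[-seq_len(n1)]),
                   tolerance = 1e-10)
  }
})

test_that("identically distributed genes are not markers and filters apply", {
  set.seed(30)
  base <- rbind(flat = rep(2, 40), filler = rep(10, 40))
  cm <- toy_counts(base)
  nm <- log_normalize(cm)
  labels <- rep(c(0, 1), each = 20)
  tab <- find_markers(cm, nm, labels)
  expect_false("flat" %in% tab$gene)        # log_fc = 0 < 0.25
  expect_error(find_markers(cm, nm, rep(0, 40)), "2 clusters")
})

test_that("planted markers are detected with high power", {
  sim <- simulate_counts(sim_count_spec(n_clusters = 3,
                                        cells_per_cluster_per_sex = 50,
                                        n_genes = 400, markers_per_cluster = 8,
                                        marker_fold = 4,
                                        artifact_rates = c(empty = 0,
                                                           high_mito = 0,
                                                           multiplet = 0),
                                        seed = 17))
  nm <- log_normalize(sim$cm)
  truth <- sim$truth$cluster
  tab <- find_markers(sim$cm, nm, truth)
  hit <- vapply(0:2, function(k)
    mean(sim$markers[[k + 1]] %in% tab$gene[tab$cluster == k]), numeric(1))
  expect_gte(mean(unlist(hit)), 0.95)
  # bonferroni column honours its definition
  expect_equal(tab$p_bonferroni,
               pmin(1, tab$p_raw * attr(tab, "params")$n_genes_tested))
})

test_that("within-cluster sex DE finds planted shifts and skips single-sex clusters", {
  set.seed(40)
  n <- 60                                  # 30 male + 30 female in cluster 0
  sexes <- rep(c("male", "female"), each = n / 2)
  biased <- c(rpois(n / 2, 9), rpois(n / 2, 2))   # male-biased gene
  flat <- rpois(n, 3)
  # large filler keeps library sizes comparable so the flat gene is not
  # compositionally distorted by the biased gene
  mat <- rbind(biased = biased, flat = flat, filler = rep(200, n))
  cm <- toy_counts(mat, sex = sexes)
  nm <- log_normalize(cm)
  labels <- rep(0, n)
  de <- find_sex_de_within_cluster(cm, nm, labels)
  expect_true("biased" %in% de$gene[de$direction == "male"])
  expect_false("flat" %in% de$gene)
  # single-sex cluster is skipped with a recorded reason
  cm_m <- toy_counts(mat[, 1:30], sex = rep("male", 30))
  de2 <- find_sex_de_within_cluster(cm_m, log_normalize(cm_m), rep(0, 30))
  expect_equal(nrow(de2), 0L)
  expect_match(attr(de2, "skipped")[["0"]], "female")
})

test_that("top_markers ranks by log fold-change with p then gene tie-breaks", {
  tab <- data.frame(cluster = c(1, 1, 1, 2),
                    gene = c("b", "a", "c", "d"),
                    p_raw = c(0.01, 0.001, 0.01, 0.04),
                    p_bonferroni = 1, log_fc = c(0.5, 0.5, 0.9, 0.3),
                    pct_in = 1, pct_out = 0)
  top <- top_markers(tab, n = 2)
  expect_equal(top$gene[top$cluster == 1], c("c", "a"))  # ties: lower p first
  expect_equal(top$gene[top$cluster == 2], "d")          # fewer than n
  expect_equal(top_markers(tab, n = 1)$gene[1], "c")
})
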