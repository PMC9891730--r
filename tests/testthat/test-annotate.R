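mk_marker_table <- function(markers_by_cluster) {
  do.call(rbind, lapply(names(markers_by_cluster), function(cl) {
    g <- markers_by_cluster[[cl]]
    if (!length(g)) return(NULL)
    data.frame(cluster = as.integer(cl), gene = g, p_raw = 0.001,
               p_bonferroni = 0.01, log_fc = 1, pct_in = 0.8, pct_out = 0.1)
  }))
}

test_that("hand rules: Hox, gamma-KC and circadian annotations", {
  tab <- mk_marker_table(list(`0` = c("Antp", "Ubx"),
                              `1` = c("ey", "sNPF", "trio"),
                              `2` = c("per", "tim"),
                              `3` = c("per")))
  ann <- annotate_clusters(tab)
  lab <- function(cl) ann$label[ann$cluster == cl]
  expect_equal(lab(0), "VNC")
  expect_equal(lab(1), "KC_gamma")
  expect_equal(ann$confidence[ann$cluster == 1], "high")
  expect_equal(lab(2), "circadian")
  expect_length(lab(3), 0)          # one clock gene is not enough
})

test_that("alpha-beta and gamma KC labels are mutually exclusive, low-confidence rule works", {
  tab <- mk_marker_table(list(`0` = c("Dop1R2", "Fas2"),
                              `1` = c("sNPF", "Fas2"),
                              `2` = c("trio", "Fas2")))
  pct <- matrix(0, nrow = 2, ncol = 3,
                dimnames = list(c("ey", "Dop1R2"), c("0", "1", "2")))
  pct["ey", "1"] <- 0.5             # ey expressed but not a marker in cluster 1
  ann <- annotate_clusters(tab, pct_expressed = pct)
  expect_equal(ann$label[ann$cluster == 0], "KC_ab")
  kc1 <- ann[ann$cluster == 1, ]
  expect_equal(kc1$label, "KC")
  expect_equal(kc1$confidence, "low")
  kc2 <- ann[ann$cluster == 2, ]
  expect_equal(kc2$label, "KC")     # trio + exactly one of Fas2/Dop1R2
  expect_false(any(ann$label %in% c("KC_ab", "KC_gamma") &
                     ann$cluster %in% c(1, 2)))
})

test_that("rule engine equals a naive re-evaluation on random marker tables", {
  rules <- annotation_rules(neuropeptides = c("NPF", "Tk"),
                            receptors = c("CrzR", "Lgr3"))
  vocab <- unique(unlist(rules))
  set.seed(70)
  for (i in 1:300) {
    markers <- sample(vocab, sample(0:8, 1))
    expressed <- union(markers, sample(vocab, sample(0:4, 1)))
    tab <- mk_marker_table(setNames(list(markers), "1"))
    pct <- matrix(0, length(vocab), 1, dimnames = list(vocab, "1"))
    pct[expressed, 1] <- 0.5
    got <- if (is.null(tab) || !length(markers)) character() else
      sort(annotate_clusters(tab, rules, pct_expressed = pct)$label)
    want <- naive_annotate(markers, expressed, rules)
    expect_equal(got, want,
                 info = paste("markers:", paste(markers, collapse = ",")))
  }
})

test_that("annotation of one cluster is unaffected by other clusters", {
  tab1 <- mk_marker_table(list(`0` = c("Antp", "VAChT")))
  tab2 <- rbind(tab1, mk_marker_table(list(`5` = c("VGlut", "SerT"))))
  a1 <- annotate_clusters(tab1)
  a2 <- annotate_clusters(tab2)
  expect_equal(a1[a1$cluster == 0, ], a2[a2$cluster == 0, ])
})

test_that("cell-level gene-set flags and the serotonergic VNC subset", {
  mat <- rbind(VAChT = c(2, 0, 0, 1), Gad1 = c(0, 1, 0, 0),
               VGlut = c(0, 0, 0, 2),
               SerT = c(1, 1, 0, 1), `abd-A` = c(0, 2, 0, 1),
               `Abd-B` = c(2, 0, 0, 0), filler = rep(5, 4))
  cm <- toy_counts(mat, sex = c("male", "female", "male", "male"))
  flags <- classify_cells_by_sets(cm, list(chol = "VAChT", gaba = "Gad1",
                                           glut = "VGlut"))$flags
  expect_equal(unname(flags[1, ]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(flags[4, ]), c(TRUE, FALSE, TRUE))   # double-flagged
  expect_equal(unname(flags[3, ]), c(FALSE, FALSE, FALSE))
  sel <- select_serotonergic_vnc(cm)
  # qualifying: cell1 (SerT+Abd-B), cell2 (SerT+abd-A), cell4 (SerT+abd-A)
  expect_setequal(sel$barcodes, cm$barcodes[c(1, 2, 4)])
  expect_equal(sel$counts_by_sex, c(male = 2L, female = 1L))
})

test_that("rules load from JSON and unknown genes only warn", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rules.json")
  jsonlite::write_json(list(neuropeptides = c("NPF", "Dh44")), path)
  rules <- read_annotation_rules(path)
  expect_equal(rules$neuropeptides, c("NPF", "Dh44"))
  expect_equal(rules$hox, c("Antp", "Ubx", "abd-A", "Abd-B"))
})
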