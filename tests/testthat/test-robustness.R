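test_that("downsampling hits the per-sex target exactly and preserves counts", {
  sim <- simulate_counts(sim_count_spec(n_clusters = 2,
                                        cells_per_cluster_per_sex = cbind(
                                          male = c(30, 30),
                                          female = c(60, 60)),
                                        n_genes = 120,
                                        artifact_rates = c(empty = 0,
                                                           high_mito = 0,
                                                           multiplet = 0),
                                        seed = 90))
  sub <- downsample(sim$cm, 60, seed = 1)
  expect_equal(sum(sub$cell_meta$sex == "male"), 60)
  expect_equal(sum(sub$cell_meta$sex == "female"), 60)
  # whole cells: every kept column identical to the source column
  idx <- match(sub$barcodes, sim$cm$barcodes)
  expect_equal(as.matrix(sub$counts), as.matrix(sim$cm$counts[, idx]))
  # identity subset and over-target error
  all_sub <- downsample(sim$cm, c(male = 60, female = 120), seed = 2)
  expect_equal(ncol(all_sub$counts), ncol(sim$cm$counts))
  expect_error(downsample(sim$cm, c(male = 61, female = 10), seed = 3),
               "exceeds")
  # two seeds give different subsets
  s1 <- downsample(sim$cm, 40, seed = 10)$barcodes
  s2 <- downsample(sim$cm, 40, seed = 11)$barcodes
  expect_false(identical(s1, s2))
})

test_that("matching a clustering to itself is the identity with rho 1", {
  sim <- simulate_counts(sim_count_spec(n_clusters = 3,
                                        cells_per_cluster_per_sex = 25,
                                        n_genes = 200, seed = 91,
                                        artifact_rates = c(empty = 0,
                                                           high_mito = 0,
                                                           multiplet = 0)))
  nm <- log_normalize(sim$cm)
  prof <- cluster_profiles(nm, sim$truth$cluster, sim$cm$gene_ids[1:100])
  m <- match_clusters(prof, prof)
  expect_equal(m$best_reference, m$query)
  expect_equal(m$rho, rep(1, nrow(m)), tolerance = 1e-12)
})

test_that("noise profiles stay unassigned and permuted labels permute matches", {
  set.seed(92)
  genes <- paste0("g", 1:80)
  ref <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(genes, 0:3))
  hits <- sapply(1:20, function(i) {
    q <- matrix(rnorm(80), 80, 1, dimnames = list(genes, "q"))
    match_clusters(ref, q)$assigned
  })
  expect_lte(mean(hits), 0.05)
  # permutation equivariance
  q <- ref + matrix(rnorm(80 * 4, sd = 0.05), 80, 4)
  colnames(q) <- colnames(ref)
  m1 <- match_clusters(ref, q)
  perm <- c("2", "0", "3", "1")
  ref_perm <- ref[, perm]
  colnames(ref_perm) <- c("a", "b", "c", "d")
  m2 <- match_clusters(ref_perm, q)
  relabel <- setNames(c("a", "b", "c", "d"), perm)
  expect_equal(unname(relabel[m1$best_reference]), m2$best_reference)
  expect_error(match_clusters(ref[1:2, , drop = FALSE],
                              q[1:2, , drop = FALSE]), "3")
})

test_that("random removal keeps labels and sex-specific classes are stable", {
  cc <- cbind(male = c(40, 40, 40), female = c(80, 80, 0))  # cluster 2 male-only
  sim <- simulate_counts(sim_count_spec(n_clusters = 3,
                                        cells_per_cluster_per_sex = cc,
                                        n_genes = 150, seed = 93,
                                        artifact_rates = c(empty = 0,
                                                           high_mito = 0,
                                                           multiplet = 0)))
  labels <- sim$truth$cluster
  for (seed in 1:3) {
    rep <- removal_composition(sim$cm, labels, c(male = 120, female = 120),
                               seed = seed)
    expect_equal(rep$class[rep$cluster == "2"], "male_specific")
  }
})

test_that("concordance report flags stable and changed clusters", {
  full <- data.frame(cluster = c("0", "1"), n_male = c(10, 10),
                     n_female_raw = c(10, 40), n_female_norm = c(10, 40),
                     ratio = c(1, 4), class = c("unbiased", "female_biased"))
  mk_run <- function(class1) {
    list(match = data.frame(query = c("0", "1"), best_reference = c("0", "1"),
                            rho = c(0.9, 0.9), assigned = TRUE),
         report = data.frame(cluster = c("0", "1"),
                             class = c("unbiased", class1)))
  }
  runs <- list(mk_run("female_biased"), mk_run("unbiased"),
               mk_run("female_biased"))
  cc <- concordance_report(full, runs)
  expect_true(cc$stable[cc$cluster == "0"])
  expect_false(cc$stable[cc$cluster == "1"])
  expect_equal(cc$changed_runs[cc$cluster == "1"], "2")
})
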