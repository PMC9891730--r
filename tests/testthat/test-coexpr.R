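test_that("Pearson correlation matches the closed form and hand example", {
  nm <- rbind(x = c(1, 0, 0), y = c(0, 1, 0), z = c(2, 0, 0))
  colnames(nm) <- paste0("c", 1:3)
  cc <- pairwise_correlation(nm, c("x", "y", "z"))
  expect_equal(cc$r["x", "y"], -0.5, tolerance = 1e-12)
  expect_equal(cc$r["x", "z"], 1, tolerance = 1e-12)     # y = 2x
  expect_equal(diag(cc$r), c(x = 1, y = 1, z = 1))
  expect_equal(cc$r, t(cc$r))
  # closed form on random vectors
  set.seed(80)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    m <- rbind(a = a, b = b)
    colnames(m) <- paste0("c", 1:15)
    r <- pairwise_correlation(m, c("a", "b"))$r["a", "b"]
    closed <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(r, closed, tolerance = 1e-12)
  }
})

test_that("correlation invariances: affine for Pearson, monotone for Spearman", {
  set.seed(81)
  a <- rnorm(20); b <- rnorm(20)
  m1 <- rbind(a = a, b = b)
  m2 <- rbind(a = 3 * a - 7, b = 0.5 * b + 2)
  colnames(m1) <- colnames(m2) <- paste0("c", 1:20)
  expect_equal(pairwise_correlation(m1, c("a", "b"))$r["a", "b"],
               pairwise_correlation(m2, c("a", "b"))$r["a", "b"],
               tolerance = 1e-12)
  m3 <- rbind(a = exp(a), b = b^3)
  colnames(m3) <- colnames(m1)
  expect_equal(pairwise_correlation(m1, c("a", "b"),
                                    method = "spearman")$r["a", "b"],
               pairwise_correlation(m3, c("a", "b"),
                                    method = "spearman")$r["a", "b"],
               tolerance = 1e-12)
})

test_that("constant genes give missing correlations and unknown genes error", {
  nm <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  colnames(nm) <- paste0("c", 1:3)
  expect_warning(cc <- pairwise_correlation(nm, c("a", "b")), "constant")
  expect_true(is.na(cc$r["a", "b"]))
  expect_error(pairwise_correlation(nm, c("a", "nope")), "nope")
})

test_that("overlap proportions partition the expressing cells", {
  # 10 cells: 5 A-only, 3 B-only, 2 A&B
  mat <- rbind(A = c(rep(1, 5), rep(0, 3), 1, 1),
               B = c(rep(0, 5), rep(1, 3), 1, 1),
               C = rep(0, 10), filler = rep(2, 10))
  cm <- toy_counts(mat)
  ov <- overlap_proportions(cm, c("A", "B", "C"))
  expect_equal(unname(ov$proportions[c("A", "B", "AB")]), c(0.5, 0.3, 0.2))
  expect_equal(sum(ov$proportions), 1, tolerance = 1e-12)
  expect_equal(ov$n_expressing, 10)
  # degenerate: nobody expresses the trio
  cm0 <- toy_counts(rbind(A = rep(0, 4), B = rep(0, 4), C = rep(0, 4),
                          filler = rep(1, 4)))
  expect_warning(ov0 <- overlap_proportions(cm0, c("A", "B", "C")),
                 "undefined")
  expect_true(all(is.na(ov0$proportions)))
  # property: exclusive fractions always sum to 1 on random data
  set.seed(82)
  for (i in 1:5) {
    m <- matrix(rbinom(3 * 30, 1, 0.4), 3, 30,
                dimnames = list(c("A", "B", "C"), NULL))
    m <- rbind(m, filler = rep(1, 30))
    cmr <- toy_counts(m)
    ovr <- suppressWarnings(overlap_proportions(cmr, c("A", "B", "C")))
    if (ovr$n_expressing > 0)
      expect_equal(sum(ovr$proportions), 1, tolerance = 1e-12)
  }
})

test_that("co-transmission proportions count co-expressing aminergic cells per sex", {
  mat <- rbind(DAT = c(1, 1, 1, 1, 0, 0), ple = rep(0, 6),
               SerT = rep(0, 6), Tdc2 = rep(0, 6),
               VAChT = c(1, 1, 1, 0, 1, 0), ChAT = rep(0, 6),
               Gad1 = rep(0, 6), VGAT = rep(0, 6), VGlut = rep(0, 6),
               filler = rep(3, 6))
  cm <- toy_counts(mat, sex = rep("male", 6))
  ct <- cotransmission(cm)
  dop_chol <- ct[ct$aminergic == "dopaminergic" & ct$fan == "cholinergic" &
                   ct$sex == "male", ]
  expect_equal(dop_chol$proportion, 0.75)   # 3 of 4 dopaminergic cells
  ser <- ct[ct$aminergic == "serotonergic" & ct$sex == "male", ]
  expect_true(all(!ser$defined))            # no SerT cells -> flagged
  expect_true(all(is.na(ser$proportion)))
})

test_that("planted co-expression rates are recovered within a binomial margin", {
  set.seed(83)
  n <- 200
  am <- rep(1, n)                           # all cells dopaminergic
  co <- rbinom(n, 1, 0.5)                   # half co-express VGlut
  mat <- rbind(DAT = am, ple = rep(0, n), SerT = rep(0, n), Tdc2 = rep(0, n),
               VAChT = rep(0, n), ChAT = rep(0, n), Gad1 = rep(0, n),
               VGAT = rep(0, n), VGlut = co, filler = rep(2, n))
  cm <- toy_counts(mat, sex = rep("male", n))
  ct <- cotransmission(cm)
  got <- ct$proportion[ct$aminergic == "dopaminergic" &
                         ct$fan == "glutamatergic" & ct$sex == "male"]
  expect_lt(abs(got - 0.5), 0.1)
})
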