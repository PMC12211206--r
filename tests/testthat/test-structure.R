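test_that("squared distances match hand computation and rescale for
           missingness", {
  # two haploid-coded individuals differing at 3 of 10 loci
  g <- cbind(rep(0L, 10), c(1L, 1L, 1L, rep(0L, 7)))
  d2 <- pairwise_distance_matrix(make_vm(g))
  expect_equal(d2[1, 2], 3)
  expect_equal(d2[1, 1], 0)
  expect_equal(d2, t(d2))

  # identical genotype vectors
  same <- cbind(rep(2L, 5), rep(2L, 5))
  expect_equal(pairwise_distance_matrix(make_vm(same))[1, 2], 0)

  # 5 of 10 loci shared, 2 differences -> 2 * (10/5)
  g <- cbind(c(rep(0L, 5), rep(NA, 5)), c(1L, 1L, 0L, 0L, 0L, rep(0L, 5)))
  expect_equal(pairwise_distance_matrix(make_vm(g))[1, 2], 4)

  # no shared locus is a hard error naming the pair
  g <- cbind(c(1L, NA), c(NA, 1L))
  expect_error(pairwise_distance_matrix(make_vm(g)),
               "ind0[12] and ind0[12] share no genotyped locus")
})

test_that("AMOVA matches the direct-summation oracle on toy data", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    d2 <- matrix(0, n, n)
    d2[upper.tri(d2)] <- runif(n * (n - 1) / 2, 0, 5)
    d2 <- d2 + t(d2)
    groups <- c("a", "a", sample(c("a", "b"), n - 2, replace = TRUE), "b")
    groups <- groups[seq_len(n)]
    if (length(unique(groups)) < 2) next
    res <- amova(d2, groups)
    orc <- amova_oracle(d2, groups)
    expect_equal(res$ss_among, orc$ss_among, tolerance = 1e-12)
    expect_equal(res$sigma2_among, orc$sigma2_among, tolerance = 1e-12)
    expect_equal(res$phi_st, orc$phi_st, tolerance = 1e-12)
    expect_equal(res$pct_among + res$pct_within, 100, tolerance = 1e-9)
  }
})

test_that("AMOVA limiting cases behave", {
  # all individuals identical
  d0 <- matrix(0, 6, 6)
  res <- amova(d0, rep(c("a", "b"), each = 3))
  expect_equal(res$phi_st, 0)
  expect_equal(res$pct_among, 0)

  # two internally-identical groups at fixed inter-group distance
  d2 <- matrix(0, 6, 6)
  d2[1:3, 4:6] <- 9
  d2[4:6, 1:3] <- 9
  res <- amova(d2, rep(c("a", "b"), each = 3))
  expect_equal(res$pct_among, 100)
  expect_equal(res$phi_st, 1)

  expect_error(amova(d0, rep("a", 6)), "2 groups")
  expect_error(amova(matrix(0, 3, 3), c("a", "b", "c")), "size 1")
})

test_that("permutation p-value is bounded, reproducible, and minimal under
           strong structure", {
  d2 <- matrix(0, 6, 6)
  d2[1:3, 4:6] <- 9
  d2[4:6, 1:3] <- 9
  groups <- rep(c("a", "b"), each = 3)
  res <- amova_permutation_test(d2, groups, n_perm = 99, seed = 2)
  # permutations preserving the partition also attain Phi = 1;
  # 2 * C(6,3)-choose pattern keeps p at its attainable floor
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  res2 <- amova_permutation_test(d2, groups, n_perm = 99, seed = 2)
  expect_equal(res$p_value, res2$p_value)

  set.seed(30)
  bn <- bn_genotypes(5, 3, 100, fst = 0.4)
  d2 <- pairwise_distance_matrix(bn$vm)
  res <- amova_permutation_test(d2, bn$pops, n_perm = 199, seed = 3)
  expect_equal(res$p_value, 1 / 200)
})

test_that("genotype PCA centres, decomposes fully, and isolates clusters", {
  set.seed(12)
  g <- matrix(rbinom(200, 2, 0.4), 20, 10)
  v <- make_vm(g)
  pca <- genotype_pca(v, n_components = 3)
  expect_equal(colMeans(pca$scores), rep(0, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(pca$explained_pct), 100, tolerance = 1e-8)
  expect_true(all(diff(pca$explained_pct) <= 1e-8))

  # two clusters of identical individuals: PC1 carries all variance
  g2 <- cbind(matrix(0L, 10, 4), matrix(2L, 10, 4))
  pca2 <- genotype_pca(make_vm(g2), n_components = 2)
  expect_equal(pca2$explained_pct[1], 100, tolerance = 1e-8)

  # zero-variance matrix degenerates to zero scores and shares
  pca0 <- genotype_pca(make_vm(matrix(1L, 5, 4)), n_components = 2)
  expect_true(all(pca0$scores == 0))
  expect_true(all(pca0$explained_pct == 0))
})

test_that("Hedrick's G'ST closed forms hold", {
  # fixed difference: p = 0 vs 1
  g <- cbind(matrix(0L, 4, 3), matrix(2L, 4, 3))
  groups <- rep(c("x", "y"), each = 3)
  res <- hedrick_gst_pairwise(make_vm(g), groups, c("x", "y"))
  expect_equal(res$mean_gst, 1)
  expect_equal(res$n_loci_used, 4)

  # identical frequencies
  g <- cbind(matrix(1L, 3, 4), matrix(1L, 3, 4))
  res <- hedrick_gst_pairwise(make_vm(g), rep(c("x", "y"), each = 4),
                              c("x", "y"))
  expect_equal(res$mean_gst, 0)

  # p = 0.2 vs 0.8: G_ST = 0.36, G'_ST = 0.36 * 1.32 / 0.68
  g <- cbind(matrix(c(1L, 1L, 0L, 0L, 0L), 1), matrix(c(2L, 2L, 2L, 1L, 1L), 1))
  groups <- rep(c("x", "y"), each = 5)
  res <- hedrick_gst_pairwise(make_vm(g), groups, c("x", "y"))
  expect_equal(res$mean_gst, 0.36 * 1.32 / 0.68, tolerance = 1e-12)

  # frequency-style inputs stay within [0, 1]
  set.seed(14)
  g <- matrix(rbinom(50 * 10, 2, runif(50, 0.2, 0.8)), 50, 10)
  res <- hedrick_gst_pairwise(make_vm(g), rep(c("x", "y"), each = 5),
                              c("x", "y"))
  expect_true(all(res$per_locus_gst > -0.5 & res$per_locus_gst <= 1 + 1e-12))

  # no usable locus
  expect_error(
    hedrick_gst_pairwise(make_vm(matrix(0L, 2, 4)),
                         rep(c("x", "y"), each = 2), c("x", "y")),
    "no usable locus")
})

test_that("G'ST density export is a proper (grid, density) table", {
  set.seed(15)
  g <- matrix(rbinom(200 * 12, 2, runif(200, 0.1, 0.9)), 200, 12)
  res <- hedrick_gst_pairwise(make_vm(g), rep(c("x", "y"), each = 6),
                              c("x", "y"))
  dens <- gst_density(res, n = 128)
  expect_named(dens, c("grid", "density"))
  expect_equal(nrow(dens), 128)
  expect_true(all(dens$density >= 0))
})

test_that("AMOVA between-group percentage tracks planted differentiation", {
  set.seed(16)
  grid <- c(0.01, 0.05, 0.1, 0.2, 0.35)
  mean_pct <- sapply(grid, function(f) {
    mean(replicate(20, {
      bn <- bn_genotypes(5, 3, 300, fst = f)
      amova(pairwise_distance_matrix(bn$vm), bn$pops)$pct_among
    }))
  })
  expect_gt(cor(grid, mean_pct, method = "spearman"), 0.95)
})
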