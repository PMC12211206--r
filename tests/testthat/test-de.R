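test_that("median-of-ratios size factors match hand computation", {
  counts <- matrix(c(2, 4, 8, 16, 50, 100), 3, 2, byrow = TRUE,
                   dimnames = list(paste0("g", 1:3), c("A", "B")))
  s <- size_factors(counts)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- matrix(5, 4, 3)
  expect_equal(unname(size_factors(same)), rep(1, 3))

  doubled <- cbind(A = c(3, 7, 11), B = 2 * c(3, 7, 11))
  s <- size_factors(doubled)
  expect_equal(unname(s[2] / s[1]), 2, tolerance = 1e-12)

  sparse <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_error(size_factors(sparse), "poscounts")
  expect_length(size_factors(sparse, method = "poscounts"), 2)
})

test_that("scaling one sample rescales its factor and leaves log2fc alone", {
  set.seed(20)
  counts <- nb_counts(200, c(4, 4), mu = 80, alpha = 0.1) + 1L
  meta <- data.frame(sample_id = colnames(counts),
                     grp = rep(c("A", "B"), each = 4))
  de1 <- nb_wald_pairwise(counts, meta, "grp", "A", "B")
  scaled <- counts
  scaled[, 1] <- scaled[, 1] * 3L
  de2 <- nb_wald_pairwise(scaled, meta, "grp", "A", "B")
  expect_equal(de2$log2fc, de1$log2fc, tolerance = 1e-9)
  # factors are defined up to the shared reference, so the *relative*
  # factor of the scaled sample grows by exactly the scaling constant
  s1 <- size_factors(counts)
  s2 <- size_factors(scaled)
  expect_equal(unname((s2[1] / s2[2]) / (s1[1] / s1[2])), 3,
               tolerance = 1e-12)
})

test_that("moment dispersion recovers the truth and clamps degenerate genes", {
  set.seed(21)
  counts <- matrix(rnbinom(100 * 5000, mu = 100, size = 1 / 0.2), 100,
                   dimnames = list(paste0("g", 1:100), NULL))
  colnames(counts) <- paste0("s", 1:5000)
  a <- dispersion_mom(counts, rep(1, 5000), rep(c("A", "B"), each = 2500))
  expect_lt(abs(median(a) / 0.2 - 1), 0.1)

  pois <- matrix(rpois(50 * 400, 100), 50)
  colnames(pois) <- paste0("s", 1:400)
  a <- dispersion_mom(pois, rep(1, 400), rep("A", 400))
  expect_lt(median(a), 0.01) # Poisson-like data collapses toward alpha_min

  const <- matrix(7, 3, 6)
  colnames(const) <- paste0("s", 1:6)
  a <- dispersion_mom(const, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(unname(a), rep(1e-8, 3))
})

test_that("identical group profiles give log2fc 0 and p 1; swapping groups
           negates the estimate", {
  counts <- matrix(rep(c(10, 60, 200), 6), 3, 6,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  meta <- data.frame(sample_id = colnames(counts),
                     grp = rep(c("A", "B"), each = 3))
  de <- nb_wald_pairwise(counts, meta, "grp", "A", "B")
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$p_raw, rep(1, 3))

  set.seed(22)
  counts <- nb_counts(150, c(5, 5), planted = list(
    list(genes = 1:20, samples = 6:10, lfc = 1.5)))
  ab <- nb_wald_pairwise(counts, meta <- data.frame(
    sample_id = colnames(counts), grp = rep(c("A", "B"), each = 5)),
    "grp", "A", "B")
  ba <- nb_wald_pairwise(counts, meta, "grp", "B", "A")
  expect_equal(ba$log2fc, -ab$log2fc, tolerance = 1e-12)
  expect_equal(ba$p_raw, ab$p_raw, tolerance = 1e-12)

  expect_error(nb_wald_pairwise(counts, meta, "grp", "A", "A"),
               "overlapping")
})

test_that("planted four-fold changes are recovered", {
  # a modest planted fraction keeps the size factors composition-neutral
  set.seed(23)
  counts <- nb_counts(400, c(5, 5), mu = 100, alpha = 0.1,
                      planted = list(list(genes = 1:20, samples = 6:10,
                                          lfc = 2)))
  meta <- data.frame(sample_id = colnames(counts),
                     grp = rep(c("A", "B"), each = 5))
  de <- nb_wald_pairwise(counts, meta, "grp", "A", "B")
  expect_lt(abs(median(de$log2fc[1:20]) - 2), 0.3)
})

test_that("all-zero genes are untested and excluded from the correction", {
  counts <- rbind(g1 = rep(0L, 6), g2 = c(5L, 6L, 4L, 50L, 60L, 40L),
                  g3 = rep(10L, 6))
  colnames(counts) <- paste0("s", 1:6)
  meta <- data.frame(sample_id = colnames(counts),
                     grp = rep(c("A", "B"), each = 3))
  de <- nb_wald_pairwise(counts, meta, "grp", "A", "B")
  expect_false(de$tested[1])
  expect_true(is.na(de$p_adj[1]))
  expect_false(de$is_deg[1])
  expect_equal(sum(de$tested), 2)
})

test_that("BH adjustment matches the hand rule and basic properties", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(24)
  p <- runif(500)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
})

test_that("DEG calling uses inclusive boundaries", {
  de <- data.frame(gene_id = paste0("g", 1:4),
                   log2fc = c(1, 0.9, -1.2, 3),
                   p_adj = c(0.01, 0.005, 0.02, 0.001),
                   tested = c(TRUE, TRUE, TRUE, FALSE))
  res <- call_degs(de, de_thresholds(0.01, 1))
  expect_equal(res$genes, "g1") # boundary case is a DEG; g4 untested
  expect_equal(res$count, 1)

  set.seed(25)
  tab <- data.frame(gene_id = paste0("g", 1:20),
                    log2fc = runif(20, -3, 3),
                    p_adj = runif(20, 0, 0.05),
                    tested = sample(c(TRUE, FALSE), 20, TRUE, c(0.9, 0.1)))
  res <- call_degs(tab, de_thresholds(0.01, 1))
  brute <- sum(tab$tested & tab$p_adj <= 0.01 & abs(tab$log2fc) >= 1)
  expect_equal(res$count, brute)
})

test_that("union counts aggregate pairwise DEG sets correctly", {
  # 3 groups; each block of 10 genes separates exactly one pair
  base <- matrix(1000, 330, 15)
  rownames(base) <- sprintf("g%03d", 1:330)
  colnames(base) <- sprintf("s%02d", 1:15)
  A <- 1:5; B <- 6:10; C <- 11:15
  base[1:10, A] <- 3000; base[1:10, C] <- 1732      # separates A vs B
  base[11:20, B] <- 3000; base[11:20, A] <- 1732    # separates B vs C
  base[21:30, C] <- 3000; base[21:30, B] <- 1732    # separates C vs A
  counts <- matrix(as.integer(base), 330, 15, dimnames = dimnames(base))
  meta <- data.frame(sample_id = colnames(counts),
                     grp = rep(c("A", "B", "C"), each = 5))
  res <- union_deg_count(counts, meta, "grp")
  expect_equal(sort(unname(res$per_pair)), c(10L, 10L, 10L))
  expect_equal(res$union_count, 30)
  expect_lte(res$union_count, sum(res$per_pair))

  # 2-group grouping: union equals the single pair's count
  res2 <- union_deg_count(counts[, 1:10], meta[1:10, ], "grp")
  expect_equal(res2$union_count, unname(res2$per_pair[1]))

  # union <= sum of per-pair counts on noisy data too
  set.seed(26)
  noisy <- nb_counts(300, c(5, 5, 5), planted = list(
    list(genes = 1:30, samples = 1:5, lfc = 2)))
  res3 <- union_deg_count(noisy, meta, "grp")
  expect_lte(res3$union_count, sum(res3$per_pair))
})
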