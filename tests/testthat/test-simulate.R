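test_that("metadata honours group sizes and is seed-deterministic", {
  cfg <- sim_config(seed = 3)
  m1 <- simulate_metadata(cfg)
  m2 <- simulate_metadata(cfg)
  expect_identical(m1, m2)
  expr <- m1[m1$in_expression, ]
  expect_equal(nrow(expr), 15)
  expect_equal(unname(table(expr$station)[c("Base", "Glacier", "Faro")]),
               c(5L, 5L, 5L), ignore_attr = TRUE)
  expect_equal(sort(unname(table(expr$mitotype))), c(2L, 3L, 3L, 7L),
               ignore_attr = TRUE)
  expect_equal(sort(unname(table(expr$nuclear_type))), c(5L, 10L),
               ignore_attr = TRUE)
  expect_equal(nrow(m1), 27)

  tiny <- sim_config(group_design = list(g = c(only = 1)),
                     geno_extra_design = list(g = c(only = 0)))
  expect_equal(nrow(simulate_metadata(tiny)), 1)
})

test_that("inconsistent grouping totals are a configuration error", {
  expect_error(
    sim_config(group_design = list(a = c(x = 5, y = 5), b = c(x = 9)),
               geno_extra_design = list(a = c(x = 0, y = 0), b = c(x = 0))),
    "inconsistent sample totals.*'a'.*'b'")
})

test_that("planted truth sets have the configured size and signs", {
  cfg <- sim_config(n_genes = 2000, de_fraction = 0.05, effect_log2fc = 2,
                    seed = 5)
  sim <- simulate_counts(cfg, simulate_metadata(cfg))
  for (g in names(cfg$group_design)) {
    truth <- sim$truth$de_genes[[g]]
    expect_equal(nrow(truth), 100)
    expect_true(all(abs(truth$log2fc) == 2))
    expect_true(all(truth$gene_id %in% rownames(sim$counts)))
  }
  cfg0 <- sim_config(de_fraction = 0, seed = 5)
  sim0 <- simulate_counts(cfg0, simulate_metadata(cfg0))
  expect_true(all(vapply(sim0$truth$de_genes, nrow, integer(1)) == 0))
})

test_that("null genes follow the NB mean-variance relation", {
  cfg <- sim_config(n_genes = 6, de_fraction = 0, dispersion = 0.3,
                    libsize_range = c(1, 1),
                    group_design = list(g = c(a = 10000)),
                    geno_extra_design = list(g = c(a = 0)),
                    seed = 11)
  sim <- simulate_counts(cfg, simulate_metadata(cfg))
  mu <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1, var)
  expected <- mu + 0.3 * mu^2
  expect_true(all(abs(v / expected - 1) < 0.15))
})

test_that("planted effects are recoverable from group-mean ratios", {
  cfg <- sim_config(n_genes = 500, de_fraction = 0.1, effect_log2fc = 1,
                    dispersion = 0.2, libsize_range = c(1, 1),
                    group_design = list(g = c(focal = 50, rest = 50)),
                    geno_extra_design = list(g = c(focal = 0, rest = 0)),
                    seed = 13)
  meta <- simulate_metadata(cfg)
  sim <- simulate_counts(cfg, meta)
  truth <- sim$truth$de_genes$g
  focal <- meta$sample_id[meta$g == "focal"]
  rest <- meta$sample_id[meta$g == "rest"]
  ratio <- rowMeans(sim$counts[truth$gene_id, focal]) /
    rowMeans(sim$counts[truth$gene_id, rest])
  # fold the sign back: planted ratio should be 2^|lfc| on the signed side
  aligned <- ifelse(truth$log2fc > 0, ratio, 1 / ratio)
  expect_lt(abs(mean(aligned) - 2), 0.15 * 2)
})

test_that("Balding-Nichols genotypes carry the planted differentiation", {
  cfg <- sim_config(n_loci_nuclear = 10000, n_loci_mito = 1,
                    fst_nuclear = 0.03, missing_rate = 0, seed = 17)
  meta <- simulate_metadata(cfg)
  v <- simulate_genotypes(cfg, meta)
  nuc <- v$geno[v$loci$contig != "contig_mito", ]
  theta <- wc_theta(nuc, meta$station)
  expect_lt(abs(theta - 0.03), 0.01)
})

test_that("fst_nuclear = 0 leaves stations with one frequency vector", {
  cfg <- sim_config(n_loci_nuclear = 3000, n_loci_mito = 1,
                    fst_nuclear = 0, missing_rate = 0, seed = 19)
  meta <- simulate_metadata(cfg)
  v <- simulate_genotypes(cfg, meta)
  nuc <- v$geno[v$loci$contig != "contig_mito", ]
  theta <- wc_theta(nuc, meta$station)
  expect_lt(abs(theta), 0.005)
})

test_that("divergent mitochondrial loci split the h1/h2 clusters on PC1", {
  cfg <- sim_config(mito_divergence = 1, het_admix = 0, missing_rate = 0,
                    n_loci_nuclear = 50, seed = 23)
  meta <- simulate_metadata(cfg)
  v <- simulate_genotypes(cfg, meta)
  mito <- partition_compartments(v, compartment_table(v))$mito
  pca <- genotype_pca(mito, n_components = 2)
  expect_gt(pca$explained_pct[1], 5 * pca$explained_pct[2])
  h1 <- meta$mitotype %in% c("h1h1", "h1h3")
  expect_gt(abs(mean(pca$scores[h1, 1]) - mean(pca$scores[!h1, 1])),
            3 * (sd(pca$scores[h1, 1]) + sd(pca$scores[!h1, 1]) + 1e-9))
})

test_that("missing_rate = 0 produces a VCF without missing codes", {
  cfg <- sim_config(missing_rate = 0, n_loci_nuclear = 50, n_loci_mito = 5,
                    seed = 29)
  v <- simulate_genotypes(cfg, simulate_metadata(cfg))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, path)
  expect_false(any(grepl("./.", readLines(path), fixed = TRUE)))
})

test_that("fixture sets round-trip losslessly through the readers", {
  cfg <- sim_config(n_genes = 60, n_loci_nuclear = 40, n_loci_mito = 8,
                    seed = 31)
  outdir <- withr::local_tempdir()
  manifest <- write_fixture_set(cfg, outdir)
  expect_equal(manifest$seed, cfg$seed)
  expect_length(manifest$files, 5)

  meta <- simulate_metadata(cfg)
  sim <- simulate_counts(cfg, meta)
  counts_back <- read_counts(file.path(outdir, "counts.tsv"))
  expect_equal(counts_back, sim$counts)
  meta_back <- read_metadata(file.path(outdir, "metadata.tsv"))
  expect_equal(meta_back$sample_id, meta$sample_id)
  expect_equal(meta_back$mitotype, meta$mitotype)

  v <- simulate_genotypes(cfg, meta)
  v_back <- read_vcf(file.path(outdir, "genotypes.vcf"))
  expect_equal(v_back$geno, v$geno)
  expect_equal(v_back$depth, v$depth)
  expect_equal(v_back$loci$contig, v$loci$contig)
  expect_equal(v_back$loci$qual, v$loci$qual, tolerance = 1e-8)
})
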