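#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a 27-individual genotyped cohort
# (stations 9/9/9) containing the 15-sample expression subset with the
# study's group sizes (stations 5/5/5, mitotypes 2/7/3/3, nuclear 10/5),
# NB counts with planted group effects, genotypes with weak nuclear station
# structure and a strong mitochondrial h1-vs-h2 split.

library(degnull)

cfg <- sim_config(seed = 1)
outdir <- "results/fixtures"
manifest <- write_fixture_set(cfg, outdir)
cat("fixture set written to", outdir, "(seed", manifest$seed, ")\n")

meta <- read_metadata(file.path(outdir, "metadata.tsv"))
counts <- read_counts(file.path(outdir, "counts.tsv"))
cat(sprintf("counts: %d genes x %d samples\n", nrow(counts), ncol(counts)))
cat("expression-cohort group sizes:\n")
expr <- meta[meta$in_expression, ]
for (g in c("station", "mitotype", "nuclear_type")) {
  tab <- table(expr[[g]])
  cat(sprintf("  %s: %s\n", g,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
}
v <- read_vcf(file.path(outdir, "genotypes.vcf"))
cat(sprintf("genotypes: %d loci x %d individuals (pre-filter)\n",
            n_loci(v), n_indiv(v)))
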