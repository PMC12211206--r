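# degnull

Are the differentially expressed genes you find between groups of animals
more than random grouping noise? `degnull` is an R package and analysis
workflow for population samples in which habitat, mitochondrial genotype
(mitotype, including heteroplasmy) and nuclear genotype may each shape gene
expression. It couples a population-genetic structure analysis (SNP
hard-filter cascade, AMOVA, PCA, Hedrick's G'ST) with pairwise
negative-binomial differential expression, and validates the observed DEG
counts against a **randomized-grouping gamma null**: the whole DE analysis
is rerun on many random groupings of the same samples with identical group
sizes, a gamma-family distribution is fitted to the null DEG counts by AIC,
and the observed count is compared with the fitted 0.95 quantile (Q0.95).

## The statistics at the core

* **Filter cascade** (VCFtools semantics): Phred ≥ 30 → max-missing 0.5 +
  MAC ≥ 3 → drop individuals with > 27% missing → minDP 10 genotype
  masking → max-missing 0.95 + MAF ≥ 0.05 + max-alleles 2, with a logged
  funnel and a mitochondrial/nuclear contig partition.
* **AMOVA** on squared Euclidean genotype distances:
  Φ_ST = σ²_among / (σ²_among + σ²_within), permutation p-value with the
  +1 rule.
* **Hedrick's G'ST** per locus: G'_ST = G_ST·(k−1+H_S)/((k−1)(1−H_S)),
  k = 2, unweighted mean allele frequencies.
* **NB Wald DE**: median-of-ratios size factors, method-of-moments
  dispersion (Var = μ + αμ²), Wald z on ln-mean differences, BH-FDR per
  comparison, DEG ⟺ p_adj ≤ 0.01 and |log2FC| ≥ 1; the per-grouping
  statistic is the union of DEG sets over all group pairs.
* **Randomization null**: n = 1,000 DEAs on random groupings of the same
  size conformation; MLE fits of {gamma, lognormal, Weibull, normal}
  selected by AIC; Q0.95 with a parametric-bootstrap confidence interval;
  verdict `observed > Q0.95`.

A synthetic-data module generates counts, genotypes and metadata with the
study's design (15 expression samples grouped 5/5/5, 2/7/3/3 and 10/5
inside a 27-individual genotyped cohort), so the full pipeline runs and is
tested without any sequencing data.

## Worked example

```r
library(degnull)

cfg <- pipeline_config(sim = sim_config(seed = 1),
                       n_iter = 200, n_perm = 200, n_boot = 200, seed = 1)
report <- run_pipeline(cfg, quiet = TRUE)
for (g in names(report$de)) {
  d <- report$de[[g]]
  cat(sprintf("%s: observed %d DEGs vs null Q0.95 %.1f -> exceeds = %s\n",
              g, d$union_count, d$null$q95, d$verdict$exceeds))
}
```

```
station: observed 77 DEGs vs null Q0.95 14.1 -> exceeds = TRUE
mitotype: observed 96 DEGs vs null Q0.95 26.4 -> exceeds = TRUE
nuclear_type: observed 97 DEGs vs null Q0.95 4.8 -> exceeds = TRUE
```

Each line is one grouping of the same 15 samples: the union DEG count over
all pairwise comparisons under the real grouping, against the 0.95 quantile
of the distribution fitted to 200 randomized-grouping DEG counts. All three
observed counts exceeding Q0.95 means each grouping captures expression
structure beyond what arbitrary groupings of these animals produce — here
by construction, since the simulation plants 5% of genes at |log2FC| = 2
per grouping.

The numbered scripts under `analysis/` run the same workflow stepwise
(simulate → filter → structure → DE → null → full pipeline) and write
their tables under `results/`.

## Package layout

* `R/` — simulation, VCF I/O and filtering, structure statistics, DE
  engine, randomization null, pipeline orchestration.
* `analysis/` — numbered narrative drivers over the package functions.
* `tests/testthat/` — unit, property and calibration tests, including
  independent brute-force oracles for the cascade, AMOVA and BH.
* `vignettes/methods.Rmd` — the full model and design account.
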