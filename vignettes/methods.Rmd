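---
title: "Methods: genotype-aware differential expression validated against a randomized-grouping gamma null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-aware differential expression validated against a randomized-grouping gamma null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

The pipeline in this package asks how three layers of biological structure
— sampling site ("station"), mitochondrial genotype ("mitotype", including
heteroplasmic individuals carrying two divergent mitochondrial haplotypes),
and nuclear genotype — modulate gene expression in a population sample of a
marine bivalve. Small group sizes (15 expression samples split 5/5/5 by
station, 2/7/3/3 by mitotype, 10/5 by nuclear type) make the central
question statistical: *are the differentially expressed gene (DEG) counts
obtained from the real groupings larger than what arbitrary groupings of
the same animals would produce?* The package answers that with a
randomization null: the entire pairwise differential-expression analysis is
rerun on many random groupings of identical size conformation, a parametric
distribution is fitted to the resulting DEG counts, and the observed count
is compared with the fitted 0.95 quantile (Q0.95).

Alongside the expression layer, the package quantifies genetic structure
from a hard-filtered SNP matrix: a two-level analysis of molecular variance
(AMOVA) between stations, genotype PCA, and pairwise Hedrick's G'ST, run
separately on mitochondrial and nuclear SNPs.

# The synthetic study design

Raw sequencing data are out of scope; a synthetic-data module generates
inputs with the statistical structure the analysis assumes. Its defaults
*are* the study conditions and are not tuned per run:

* **Cohorts.** 27 genotyped individuals (stations 9/9/9), of which 15 form
  the expression cohort with group sizes 5/5/5 (station), 2/7/3/3
  (mitotype: homoplasmic h1h1 and h2h2, heteroplasmic h1h3 and h2h3) and
  10/5 (nuclear type).
* **Counts.** `K ~ NB(mu, alpha)` with `Var = mu + alpha*mu^2`,
  `alpha = 0.2` (a typical bulk RNA-seq overdispersion), 2,000 genes,
  gene baselines log-normal (meanlog 4, sdlog 1 on the count scale — the
  field's usual heavy-tailed abundance shape; no per-group baseline
  information was available, so one shared baseline distribution is used),
  library-size factors log-uniform on [0.5, 2] (heavy-tailed realism
  without extra parameters).
* **Planted effects.** 5% of genes per grouping receive a signed
  |log2FC| = 2 in one contrast per grouping: first station vs the rest,
  homoplasmic vs heteroplasmic mitotypes (the dominant expression pattern
  in this system), and NucA vs NucB. One contrast per grouping mirrors the
  dominant observed patterns without combinatorial truth bookkeeping.
* **Genotypes.** Nuclear loci follow a Balding–Nichols model at
  `F_ST = 0.03` between stations (weak spatial structure). Mitochondrial
  loci are clonal: the h1-carrying and h2-carrying clusters differ at 80%
  of 145 mito loci, and heteroplasmic individuals show intermediate dosage
  at 25% of those divergent sites, mimicking minor-haplotype admixture.
  Mitotypes are effectively haploid lineages, so mito genotypes take the
  homozygous codes with heterozygous codes only at admixed sites.
* **Noise layers.** Per-site Phred quality uniform on [20, 60] (so a
  Phred ≥ 30 filter removes a predictable ≈25% of sites), per-genotype
  depth Poisson(20) (matching minDP masking semantics), genotypes missing
  independently at 5%.

What the generator does **not** emulate: read-level errors, assembly
artifacts, mapping bias, gene–gene correlation, sample-level batch
effects, or sex/tissue structure. Passing tests therefore demonstrate the
*procedures* are correct and calibrated under the assumed model, not that
the model captures every property of real sequencing data.

# SNP filter cascade

The cascade follows VCFtools semantics (the convention the thresholds are
phrased in): `max-missing f` keeps loci genotyped in at least a fraction
`f` of individuals; `minDP` masks genotypes, it does not drop sites. The
fixed stage order is:

1. site Phred quality ≥ 30 (strictly below excluded);
2. stage-1 site filter: max-missing 0.5, minor allele count ≥ 3;
3. individuals with **more than** 27% missing data removed (strict);
4. per-genotype masking at minDP 10;
5. stage-2 site filter: max-missing 0.95, minor allele frequency ≥ 0.05,
   max-alleles 2.

MAC and MAF are computed over non-missing genotypes; a frequency of
exactly 0.5 counts both alleles as minor (MAF = 0.5). Stage-1 MAC is
computed on unmasked genotypes: the depth mask belongs to the second
filtering step, and is applied immediately before the stage-2 site
predicates. This ordering is observable (a fully genotyped locus with a few
under-covered cells passes stage 1 but falls at stage 2) and is pinned by a
regression test. Multi-allelic records are carried with dosage counted
against the first ALT allele until max-alleles removes them; with default
parameters they never survive. Loci on contigs not listed as mitochondrial
are treated as nuclear ("no hit" means nuclear).

# Population structure

**AMOVA.** Distance-based (Excoffier-style) variance partition on squared
Euclidean genotype distances, `d²(i,j)` computed over loci non-missing in
both individuals and rescaled by (total loci / shared loci). With `N`
individuals in `G` groups of sizes `n_g`:

$$SS_{tot} = \frac{1}{N}\sum_{i<j} d^2_{ij},\qquad
  SS_{w} = \sum_g \frac{1}{n_g}\sum_{i<j\in g} d^2_{ij},\qquad
  SS_{a} = SS_{tot} - SS_{w}$$

with `df_a = G-1`, `df_w = N-G`,
`sigma²_w = SS_w/df_w`,
`sigma²_a = (SS_a/df_a − sigma²_w)/n̄` where
`n̄ = (N − Σ n_g²/N)/(G−1)`, and
`Phi_ST = sigma²_a/(sigma²_a + sigma²_w)`. The among-group component may be
negative on unstructured data; it is reported as-is (the test statistic
stays unbiased) and percentages are floored at zero only in the report
tables. Significance is by permutation of group labels,
`p = (1 + \#\{Phi_{perm} \ge Phi_{obs}\})/(n_{perm}+1)` — the +1 rule keeps
p strictly positive. An all-identical input defines `Phi = 0`.

**PCA.** Missing dosages are mean-imputed per locus, loci are centred but
not scaled (covariance PCA on dosages, the ecosystem default; scaling is a
switch), and scores come from the SVD. Explained percentages are
eigenvalue shares of the full decomposition.

**Hedrick's G'ST.** Per biallelic locus with `k = 2` groups:
`H_S = mean(2p_g(1−p_g))`, `H_T = 2p̄(1−p̄)` with `p̄` the *unweighted*
mean of the two group frequencies (group sizes here are small and unequal;
equal weights keep the estimator symmetric and easy to verify),
`G_ST = (H_T−H_S)/H_T` and `G'_{ST} = G_{ST}(k−1+H_S)/((k−1)(1−H_S))`.
Loci with `H_T = 0` or `H_S = 1` are skipped; finite-sample estimates may
fall slightly outside [0,1] and are reported unclamped. Density summaries
use a Gaussian KDE with Silverman's rule-of-thumb bandwidth.

# Differential expression engine

The engine is a deliberately transparent negative-binomial Wald test,
authored in this package rather than delegated, because the validation
layer is calibration-based: what matters is that the identical procedure is
applied to the original and to randomized groupings, and that its null
behaviour is checked empirically.

* **Normalization**: median-of-ratios size factors
  `s_j = median_g (K_{gj}/\text{geomean}_g)` over genes positive in all
  samples, with a `poscounts`-style fallback for sparse matrices.
* **Dispersion**: per-gene method of moments on normalized counts — pooled
  within-group variance `v`, grand mean `μ̂`, and
  `α̂ = (v − μ̂\,\overline{1/s})/μ̂²` clamped to `[10^{-8}, 10]`. No
  empirical-Bayes shrinkage; with 5–10 samples per group the clamp and the
  randomization calibration carry the robustness burden instead.
* **Test**: group means of normalized counts; a zero group mean is replaced
  by the continuity value `0.5/Σ_{j∈g} s_j` so log fold changes stay
  finite; `λ = ln μ̂_B − ln μ̂_A`,
  `Var(\ln μ̂_g) = [Σ_{j∈g}(μ̂_g/s_j + α μ̂_g²)]/(n_g μ̂_g)²`,
  `z = λ/\sqrt{Var_A + Var_B}`, two-sided normal p. Genes all-zero in both
  groups are untested.
* **Correction and calling**: Benjamini–Hochberg within each pairwise
  comparison over its tested genes; DEG iff `p_{adj} ≤ 0.01` **and**
  `|log2FC| ≥ 1`, both inclusive. The per-grouping statistic is the size of
  the union of DEG sets over all unordered group pairs (a gene counted once
  however many pairs flag it).

The measured type-I error of the raw Wald p at nominal 0.05 is ~0.06–0.07
on 10-vs-10 null NB data — the small-sample anticonservativeness expected
of a normal-approximation Wald test, and one reason the final inference
leans on the randomization null rather than on raw p-values.

# Randomization null, gamma fit, Q0.95

For each grouping the full pairwise DEA is rerun `n_iter = 1000` times
(default) on groupings drawn uniformly at random with the original size
conformation; groupings are sampled with replacement across iterations —
the partition space for 15 samples is astronomically larger than the
iteration count. Size factors are estimated once per matrix (they do not
depend on grouping); dispersions are re-estimated per randomized grouping.

Candidate distributions {gamma, lognormal, Weibull, normal} are fitted by
maximum likelihood and compared by `AIC = 2k − 2\logL`. The candidate set
is the minimal conventional one that makes model selection meaningful
while defaulting to gamma on gamma-like data. If any null count is ≤ 0
(common: many randomized analyses yield zero DEGs), positive-support
candidates are fitted on values shifted by +0.5 and quantiles are shifted
back (floored at 0); the shift is recorded in the fit object.

`Q0.95` is the inverse CDF of the selected distribution at 0.95. Its
confidence interval is a parametric bootstrap — resample `n_iter` values
from the fitted distribution, refit within the family, take the percentile
interval of the resampled quantiles. A closed-form quantile interval for
the gamma exists, but the bootstrap is family-agnostic (the AIC winner need
not be gamma) and its coverage is verified by simulation in the test
suite; the exceedance verdict depends only on the point estimate, not the
interval. The verdict is strict: `exceeds ⟺ observed > Q0.95`. An empirical
permutation p-value `(1 + \#\{null ≥ observed\})/(n_{iter}+1)` is reported
alongside as a distribution-free cross-check.

# Numerical and design choices

* Boundary semantics are literal throughout: "below 30" strict, "more than
  27%" strict, max-missing/MAF/DEG thresholds inclusive.
* Degenerate inputs have defined behaviour: empty VCFs flow through the
  cascade as 0-locus matrices; an all-equal null sample is an error (no
  distribution can be selected); a zero-variance genotype matrix yields
  zero PCA scores and shares; all-size-1 AMOVA groups are an error.
* Determinism: every stochastic stage takes an explicit seed, and the
  pipeline derives per-stage seeds from one master seed; two runs with the
  same configuration produce byte-identical JSON reports.
* Problem sizes in the test suite are chosen to exercise each property at
  desk scale (e.g. 2,000-gene matrices, 200-replicate calibration runs
  with 200 randomizations each, 10,000-locus differentiation checks);
  the pipeline defaults (1,000 randomizations, 1,000 permutations, 1,000
  bootstrap resamples) match the analysis they reproduce.

# Known limitations

* The Wald test is anticonservative at very small group sizes (n = 2);
  the randomization null absorbs this for the exceedance question, but
  per-gene p-values from such comparisons should be read with care.
* Method-of-moments dispersions are noisy per gene; they are not shrunk,
  so this engine is a calibration-grade reimplementation, not a drop-in
  replacement for shrinkage-based DE tools on real data.
* AMOVA here is two-level only (groups / individuals within groups).
* G'ST assumes biallelic loci and two groups per comparison.
* The randomization preserves only the size conformation — it does not
  stratify by the other groupings, so the null for one grouping includes
  label arrangements correlated with another grouping's true structure.
  This matches the free-randomization design the procedure validates.
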