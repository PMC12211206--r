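#' Differential-expression calling thresholds
#'
#' @param alpha_adj BH-adjusted p-value cutoff (inclusive).
#' @param min_abs_log2fc minimum absolute log2 fold change (inclusive;
#'   the default 1 means a fold change of at least 2).
#' @return A `de_thresholds` list.
#' @export
de_thresholds <- function(alpha_adj = 0.01, min_abs_log2fc = 1) {
  stopifnot(alpha_adj > 0, alpha_adj < 1, min_abs_log2fc >= 0)
  structure(list(alpha_adj = alpha_adj, min_abs_log2fc = min_abs_log2fc),
            class = "de_thresholds")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference genes of the ratio of its
#' count to the gene's geometric mean across samples. With
#' `method = "ratio"` the reference genes are those with strictly positive
#' counts in every sample; `method = "poscounts"` computes geometric means
#' over positive counts only (zeros excluded) and takes medians over
#' positive ratios, for sparse matrices where no gene is positive
#' everywhere. Poscounts factors are rescaled to geometric mean 1.
#'
#' @param counts integer matrix, genes x samples.
#' @param method `"ratio"` (default) or `"poscounts"`.
#' @return positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts, method = c("ratio", "poscounts")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (method == "ratio") {
    allpos <- rowSums(counts <= 0) == 0
    if (!any(allpos))
      stop("no gene has positive counts in all samples; ",
           "use size_factors(method = \"poscounts\")")
    lg <- log(counts[allpos, , drop = FALSE])
    ref <- rowMeans(lg)
    s <- apply(exp(lg - ref), 2, stats::median)
  } else {
    lg <- log(counts)
    lg[!is.finite(lg)] <- NA
    ref <- rowMeans(lg, na.rm = TRUE)
    ok <- is.finite(ref)
    ratios <- exp(lg[ok, , drop = FALSE] - ref[ok])
    s <- apply(ratios, 2, stats::median, na.rm = TRUE)
    s <- s / exp(mean(log(s)))
  }
  stats::setNames(s, colnames(counts))
}

#' Method-of-moments per-gene NB dispersion
#'
#' On normalized counts `q = K/s`, computes the pooled within-group variance
#' `v` and grand mean `mu_hat` per gene and estimates
#' `alpha_hat = (v - mu_hat * mean_j(1/s_j)) / mu_hat^2`, clamped to
#' `[alpha_min, alpha_max]`. Genes with zero grand mean get `alpha_min`.
#'
#' @param counts integer matrix, genes x samples.
#' @param sf size factors from [size_factors()].
#' @param grouping group label per sample (pooling is within these groups).
#' @param alpha_min,alpha_max clamp bounds.
#' @return numeric vector of per-gene dispersions.
#' @export
dispersion_mom <- function(counts, sf, grouping,
                           alpha_min = 1e-8, alpha_max = 10) {
  q <- sweep(as.matrix(counts), 2, sf, "/")
  groups <- unique(grouping)
  N <- ncol(q)
  G <- length(groups)
  if (N - G < 1) stop("need at least one group with >=2 samples")
  ss <- 0
  for (g in groups) {
    idx <- grouping == g
    if (sum(idx) > 1) {
      qg <- q[, idx, drop = FALSE]
      ss <- ss + rowSums((qg - rowMeans(qg))^2)
    }
  }
  v <- ss / (N - G)
  mu <- rowMeans(q)
  alpha <- ifelse(mu > 0, (v - mu * mean(1 / sf)) / mu^2, alpha_min)
  pmin(pmax(alpha, alpha_min), alpha_max)
}

# Vectorized core of the pairwise Wald test: operates on pre-normalized
# counts. Returns the per-gene test table.
nb_wald_core <- function(q, sf, idx_a, idx_b, alpha, thresholds) {
  n_a <- length(idx_a)
  n_b <- length(idx_b)
  qa <- q[, idx_a, drop = FALSE]
  qb <- q[, idx_b, drop = FALSE]
  mu_a <- rowMeans(qa)
  mu_b <- rowMeans(qb)
  tested <- !(mu_a == 0 & mu_b == 0)
  # continuity substitute keeps log fold changes finite for one-sided zeros
  pseudo_a <- 0.5 / sum(sf[idx_a])
  pseudo_b <- 0.5 / sum(sf[idx_b])
  ma <- ifelse(mu_a == 0, pseudo_a, mu_a)
  mb <- ifelse(mu_b == 0, pseudo_b, mu_b)
  lambda <- log(mb) - log(ma)
  var_ln <- function(mu, idx, n) {
    (mu * sum(1 / sf[idx]) + alpha * mu^2 * n) / (n * mu)^2
  }
  se2 <- var_ln(ma, idx_a, n_a) + var_ln(mb, idx_b, n_b)
  se <- sqrt(se2)
  z <- lambda / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_raw[!tested] <- NA_real_
  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[tested] <- bh_adjust(p_raw[tested])
  log2fc <- lambda / log(2)
  is_deg <- tested & !is.na(p_adj) &
    p_adj <= thresholds$alpha_adj &
    abs(log2fc) >= thresholds$min_abs_log2fc
  data.frame(gene_id = rownames(q), base_mean_a = mu_a, base_mean_b = mu_b,
             log2fc = log2fc, se = se / log(2), p_raw = p_raw, p_adj = p_adj,
             tested = tested, is_deg = is_deg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise negative-binomial Wald test
#'
#' Tests each gene for differential expression between two sample groups.
#' Group means are means of median-of-ratios-normalized counts; the Wald
#' statistic uses the delta-method variance of the log mean under
#' `Var(K) = s*mu + alpha*(s*mu)^2`:
#' `Var(ln mu_g) = [sum_j(mu_g/s_j + alpha*mu_g^2)] / (n_g*mu_g)^2`.
#' Two-sided normal p-values are BH-adjusted over the tested genes of this
#' comparison (genes with all-zero counts in both groups are untested and
#' excluded from the correction). A group with zero mean is substituted by
#' the continuity value `0.5 / sum(s_j in group)` before taking logs.
#'
#' @param counts integer matrix, genes x samples (gene ids as rownames).
#' @param meta metadata data.frame with `sample_id` and the grouping column.
#' @param group_by name of the grouping column in `meta`.
#' @param group_a,group_b the two group labels to compare (log2 fold change
#'   is B relative to A).
#' @param thresholds a [de_thresholds()].
#' @param alpha optional per-gene dispersion vector; computed from the two
#'   groups' samples by [dispersion_mom()] when missing.
#' @return data.frame: `gene_id`, `base_mean_a`, `base_mean_b`, `log2fc`,
#'   `se`, `p_raw`, `p_adj`, `tested`, `is_deg`.
#' @export
nb_wald_pairwise <- function(counts, meta, group_by, group_a, group_b,
                             thresholds = de_thresholds(), alpha = NULL) {
  stopifnot(group_by %in% names(meta))
  labels <- meta[[group_by]][match(colnames(counts), meta$sample_id)]
  idx_a <- which(labels == group_a)
  idx_b <- which(labels == group_b)
  if (length(idx_a) == 0 || length(idx_b) == 0)
    stop("empty group in comparison ", group_a, " vs ", group_b)
  if (length(intersect(idx_a, idx_b)) > 0)
    stop("overlapping groups ", group_a, " and ", group_b)
  sub <- counts[, c(idx_a, idx_b), drop = FALSE]
  sf <- size_factors(sub)
  q <- sweep(sub, 2, sf, "/")
  if (is.null(alpha)) {
    grouping <- c(rep("A", length(idx_a)), rep("B", length(idx_b)))
    alpha <- dispersion_mom(sub, sf, grouping)
  }
  nb_wald_core(q, sf, seq_along(idx_a),
               length(idx_a) + seq_along(idx_b), alpha, thresholds)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR correction (monotone minimum of `m * p_(k) / k` from the
#' largest rank down, capped at 1).
#'
#' @param p vector of p-values in \[0,1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("NA/NaN p-values passed to bh_adjust")
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes from a test table
#'
#' A gene is a DEG iff it was tested, `p_adj <= alpha_adj` and
#' `|log2fc| >= min_abs_log2fc` (both thresholds inclusive).
#'
#' @param de a table from [nb_wald_pairwise()].
#' @param thresholds a [de_thresholds()].
#' @return list with `genes` (identifiers) and `count`.
#' @export
call_degs <- function(de, thresholds = de_thresholds()) {
  hit <- de$tested & !is.na(de$p_adj) &
    de$p_adj <= thresholds$alpha_adj &
    abs(de$log2fc) >= thresholds$min_abs_log2fc
  list(genes = de$gene_id[hit], count = sum(hit))
}

# Precompute normalization shared by the many pairwise tests run over a
# single count matrix (the randomization null re-tests the same matrix
# hundreds of times).
de_prepare <- function(counts) {
  counts <- as.matrix(counts)
  sf <- size_factors(counts)
  list(counts = counts, sf = sf, q = sweep(counts, 2, sf, "/"))
}

# union_deg_count on a prepared object and an integer-index grouping;
# dispersion is estimated once from the full grouping and shared across
# its pairwise comparisons.
union_deg_count_prepared <- function(prep, group_idx, thresholds) {
  labels <- names(group_idx)
  grouping <- character(ncol(prep$counts))
  for (g in labels) grouping[group_idx[[g]]] <- g
  alpha <- dispersion_mom(prep$counts, prep$sf, grouping)
  per_pair <- list()
  union_genes <- character(0)
  for (i in seq_along(labels)[-length(labels)]) {
    for (j in seq((i + 1), length(labels))) {
      de <- nb_wald_core(prep$q, prep$sf, group_idx[[labels[i]]],
                         group_idx[[labels[j]]], alpha, thresholds)
      hits <- de$gene_id[de$is_deg]
      per_pair[[paste(labels[i], labels[j], sep = "_vs_")]] <- length(hits)
      union_genes <- union(union_genes, hits)
    }
  }
  list(per_pair = unlist(per_pair), union_count = length(union_genes),
       union_genes = union_genes)
}

#' DEG counts across all pairwise comparisons of a grouping
#'
#' Runs the NB Wald test for every unordered pair of groups and returns the
#' per-pair DEG counts and the size of the union of DEG sets — the
#' analysis-level statistic the randomization null is built on. Size
#' factors and dispersions are estimated once on the full matrix/grouping
#' and shared across pairs.
#'
#' @param counts integer matrix, genes x samples.
#' @param meta metadata with `sample_id` and the grouping column.
#' @param group_by grouping column name.
#' @param thresholds a [de_thresholds()].
#' @return list with `per_pair` (named integer vector), `union_count` and
#'   `union_genes`.
#' @export
union_deg_count <- function(counts, meta, group_by,
                            thresholds = de_thresholds()) {
  labels_per_sample <- meta[[group_by]][match(colnames(counts),
                                              meta$sample_id)]
  groups <- unique(labels_per_sample)
  if (length(groups) < 2) stop("grouping needs at least 2 groups")
  group_idx <- lapply(stats::setNames(groups, groups),
                      function(g) which(labels_per_sample == g))
  union_deg_count_prepared(de_prepare(counts), group_idx, thresholds)
}
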