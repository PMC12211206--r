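#' Pairwise squared-Euclidean genotype distance matrix
#'
#' For each pair of individuals, the squared Euclidean distance over loci
#' non-missing in both, rescaled by (total loci / shared loci) so that pairs
#' with different amounts of shared data are comparable. This is the
#' distance the variance partition in [amova()] consumes.
#'
#' @param v a [variant_matrix()] with at least 2 individuals.
#' @return symmetric numeric matrix of squared distances, zero diagonal,
#'   dimnames = sample ids.
#' @export
pairwise_distance_matrix <- function(v) {
  n <- n_indiv(v)
  if (n < 2) stop("need at least 2 individuals")
  L <- n_loci(v)
  g <- v$geno
  obs <- !is.na(g)
  g0 <- g
  g0[!obs] <- 0
  # shared-loci counts and raw squared distances via cross-products:
  # d2_raw(i,j) = sum over loci observed in both of (g_i - g_j)^2
  shared <- crossprod(obs)
  gg <- crossprod(g0)
  si <- crossprod(g0^2, obs) # si[i,j] = sum_l g_li^2 * obs_lj
  d2_raw <- si + t(si) - 2 * gg
  if (any(shared == 0 & row(shared) != col(shared))) {
    bad <- which(shared == 0 & row(shared) != col(shared), arr.ind = TRUE)[1, ]
    stop(sprintf("individuals %s and %s share no genotyped locus",
                 v$samples[bad[1]], v$samples[bad[2]]))
  }
  d2 <- d2_raw * (L / shared)
  diag(d2) <- 0
  dimnames(d2) <- list(v$samples, v$samples)
  d2
}

# Phi_ST and variance components from a squared-distance matrix and integer
# group codes; the computational core shared by amova() and its permutation
# test.
amova_components <- function(d2, groups) {
  N <- nrow(d2)
  g <- as.integer(factor(groups))
  G <- max(g)
  n_g <- tabulate(g, G)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (k in seq_len(G)) {
    idx <- which(g == k)
    if (length(idx) > 1) {
      dk <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(dk[upper.tri(dk)]) / n_g[k]
    }
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1L
  df_within <- N - G
  if (df_within == 0) stop("all groups of size 1: no within-group df")
  ms_among <- ss_among / df_among
  sigma2_within <- ss_within / df_within
  n_bar <- (N - sum(n_g^2) / N) / (G - 1)
  sigma2_among <- (ms_among - sigma2_within) / n_bar
  tot <- sigma2_among + sigma2_within
  phi <- if (tot == 0) 0 else sigma2_among / tot
  list(df_among = df_among, df_within = df_within,
       ss_among = ss_among, ss_within = ss_within,
       sigma2_among = sigma2_among, sigma2_within = sigma2_within,
       phi_st = phi)
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Distance-based variance partition between groups ("among", e.g. between
#' stations) and within groups (among individuals), from squared genotype
#' distances: `SS_total = (1/N) sum_{i<j} d2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d2`, variance components from
#' the mean squares with the unequal-size coefficient
#' `n_bar = (N - sum(n_g^2)/N) / (G-1)`, and
#' `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`. A degenerate
#' all-identical input yields Phi = 0 and 0% among-group variance. The
#' among-group component may legitimately be negative; it is reported as-is
#' (percentages are floored at zero only in the report layer).
#'
#' @param d2 squared-distance matrix from [pairwise_distance_matrix()].
#' @param groups group label per individual (same order as `d2` rows).
#' @return list of class `amova_result`: degrees of freedom, sums of
#'   squares, variance components, percentages, `phi_st` (and `p_value` NA
#'   until [amova_permutation_test()] fills it).
#' @export
amova <- function(d2, groups) {
  stopifnot(nrow(d2) == length(groups))
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  cmp <- amova_components(d2, groups)
  tot <- cmp$sigma2_among + cmp$sigma2_within
  pct_among <- if (tot == 0) 0 else 100 * cmp$sigma2_among / tot
  structure(c(cmp, list(pct_among = pct_among,
                        pct_within = 100 - pct_among,
                        p_value = NA_real_)),
            class = "amova_result")
}

#' Permutation test for AMOVA
#'
#' Permutes individual group labels uniformly `n_perm` times and reports
#' `p = (1 + #[Phi_perm >= Phi_obs]) / (n_perm + 1)`.
#'
#' @param d2 squared-distance matrix.
#' @param groups group label per individual.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return The [amova()] result with `p_value` filled in and `n_perm`
#'   recorded.
#' @export
amova_permutation_test <- function(d2, groups, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  res <- amova(d2, groups)
  set.seed(seed)
  phi_obs <- res$phi_st
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    phi_p <- amova_components(d2, sample(groups))$phi_st
    if (phi_p >= phi_obs) exceed <- exceed + 1L
  }
  res$p_value <- (1 + exceed) / (n_perm + 1)
  res$n_perm <- n_perm
  res
}

#' Genotype principal component analysis
#'
#' Mean-imputes missing dosages per locus, centres each locus, and
#' decomposes the individuals-by-loci matrix by SVD (covariance PCA; loci
#' are not scaled to unit variance — set `scale = TRUE` to change that).
#' Explained percentages are eigenvalue shares of the total variance.
#'
#' @param v a [variant_matrix()].
#' @param n_components number of components to return scores for.
#' @param scale logical; scale loci to unit variance before the SVD.
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `explained_pct` (all components of the full decomposition).
#' @export
genotype_pca <- function(v, n_components = 2, scale = FALSE) {
  if (n_indiv(v) < 2 || n_loci(v) < 1) stop("need >=2 individuals, >=1 locus")
  x <- t(v$geno)
  for (l in seq_len(ncol(x))) {
    m <- mean(x[, l], na.rm = TRUE)
    if (is.nan(m)) m <- 0
    x[is.na(x[, l]), l] <- m
  }
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) {
    k <- min(n_components, nrow(x) - 1)
    return(structure(list(
      scores = matrix(0, nrow(x), k,
                      dimnames = list(v$samples, paste0("PC", seq_len(k)))),
      explained_pct = rep(0, k)), class = "pca_result"))
  }
  if (scale) x <- x[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  k <- min(n_components, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 explained_pct = 100 * ev / sum(ev)),
            class = "pca_result")
}

#' Hedrick's standardized G'ST between two groups
#'
#' Per biallelic locus with k = 2 subpopulations: within-group expected
#' heterozygosity `H_S = mean(2 p_g (1 - p_g))`, total heterozygosity
#' `H_T = 2 p_bar (1 - p_bar)` with `p_bar` the unweighted mean of the two
#' group frequencies, `G_ST = (H_T - H_S)/H_T`, and Hedrick's rescaling
#' `G'_ST = G_ST (k - 1 + H_S) / ((k - 1)(1 - H_S))`. Loci with `H_T = 0`
#' (no variation) or `H_S = 1` are skipped. Allele frequencies use
#' non-missing genotypes only. Estimates on finite samples may fall slightly
#' outside \[0,1\] and are reported unclamped.
#'
#' @param v a [variant_matrix()].
#' @param groups group label per individual.
#' @param pair length-2 character: the two group labels to compare.
#' @return list of class `gst_result`: `pair`, `per_locus_gst`, `mean_gst`,
#'   `n_loci_used`.
#' @export
hedrick_gst_pairwise <- function(v, groups, pair) {
  stopifnot(length(pair) == 2, all(pair %in% groups))
  freq_of <- function(label) {
    g <- v$geno[, groups == label, drop = FALSE]
    called <- rowSums(!is.na(g))
    ifelse(called > 0, rowSums(g, na.rm = TRUE) / (2 * called), NA_real_)
  }
  p1 <- freq_of(pair[1])
  p2 <- freq_of(pair[2])
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  usable <- !is.na(hs) & !is.na(ht) & ht > 0 & hs < 1
  if (!any(usable)) stop(sprintf(
    "no usable locus for G'ST between %s and %s", pair[1], pair[2]))
  gst <- (ht[usable] - hs[usable]) / ht[usable]
  gst_p <- gst * (1 + hs[usable]) / (1 - hs[usable]) # k = 2
  structure(list(pair = pair, per_locus_gst = gst_p,
                 mean_gst = mean(gst_p), n_loci_used = sum(usable)),
            class = "gst_result")
}

#' Kernel density summary of per-locus G'ST values
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth, for export as a
#' (grid, density) table.
#'
#' @param gst a `gst_result` from [hedrick_gst_pairwise()].
#' @param n grid size.
#' @return data.frame with columns `grid`, `density`.
#' @export
gst_density <- function(gst, n = 512) {
  d <- stats::density(gst$per_locus_gst, bw = "nrd0", n = n)
  data.frame(grid = d$x, density = d$y)
}
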