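# Shared fixture builders and independent oracles.

# Small variant matrix from explicit pieces; qual/depth default to values
# that pass every filter so tests can plant single failures.
make_vm <- function(geno, qual = NULL, depth = NULL, contig = NULL,
                    n_alleles = NULL) {
  geno <- as.matrix(geno)
  L <- nrow(geno)
  n <- ncol(geno)
  if (is.null(qual)) qual <- rep(50, L)
  if (is.null(depth)) depth <- matrix(30L, L, n)
  if (is.null(contig)) contig <- sprintf("ctg%03d", seq_len(L))
  if (is.null(n_alleles)) n_alleles <- rep(2L, L)
  # ALT strings mirror the allele number so VCF round-trips preserve it
  alt <- vapply(n_alleles, function(k)
    paste(c("C", "G", "T")[seq_len(k - 1)], collapse = ","), character(1))
  loci <- data.frame(contig = contig, pos = seq_len(L) * 10L,
                     ref = rep_len("A", L), alt = alt,
                     n_alleles = n_alleles, qual = qual,
                     stringsAsFactors = FALSE)
  variant_matrix(loci, geno, depth, sprintf("ind%02d", seq_len(n)))
}

# Brute-force AMOVA oracle: direct summation over all pairs, scalar loops.
amova_oracle <- function(d2, groups) {
  N <- nrow(d2)
  labs <- unique(groups)
  G <- length(labs)
  ss_total <- 0
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N)) {
    ss_total <- ss_total + d2[i, j]
  }
  ss_total <- ss_total / N
  ss_within <- 0
  for (lab in labs) {
    idx <- which(groups == lab)
    if (length(idx) < 2) next
    acc <- 0
    for (a in seq_len(length(idx) - 1)) for (b in seq(a + 1, length(idx))) {
      acc <- acc + d2[idx[a], idx[b]]
    }
    ss_within <- ss_within + acc / length(idx)
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1
  df_within <- N - G
  s2_within <- ss_within / df_within
  n_g <- sapply(labs, function(l) sum(groups == l))
  n_bar <- (N - sum(n_g^2) / N) / (G - 1)
  s2_among <- (ss_among / df_among - s2_within) / n_bar
  list(ss_among = ss_among, ss_within = ss_within,
       sigma2_among = s2_among, sigma2_within = s2_within,
       phi_st = if (s2_among + s2_within == 0) 0 else
         s2_among / (s2_among + s2_within))
}

# Brute-force BH step-up from the definition:
# p_adj(i) = min over k >= rank(i) of m * p_(k) / k, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (r in seq_len(m)) {
    adj[r] <- min(1, min(m * ps[r:m] / (r:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent predicate-scan of the filter cascade: per-locus loops, no
# shared code with run_filter_cascade. Returns per-stage survivor counts.
cascade_oracle <- function(v, p) {
  geno <- v$geno
  depth <- v$depth
  qual <- v$loci$qual
  nall <- v$loci$n_alleles
  n_ind <- ncol(geno)
  keep <- which(qual >= p$min_qual)
  log <- list(site_quality = c(length(qual), length(keep), n_ind, n_ind))

  s1 <- integer(0)
  for (l in keep) {
    g <- geno[l, ]
    called <- sum(!is.na(g))
    if (called / n_ind < p$stage1_max_missing) next
    alt <- sum(g, na.rm = TRUE)
    mac <- min(alt, 2 * called - alt)
    if (mac < p$mac_min) next
    s1 <- c(s1, l)
  }
  log$stage1_sites <- c(length(keep), length(s1), n_ind, n_ind)

  keep_ind <- integer(0)
  for (j in seq_len(n_ind)) {
    miss <- mean(is.na(geno[s1, j]))
    if (miss <= p$indiv_max_missing) keep_ind <- c(keep_ind, j)
  }
  log$individuals <- c(length(s1), length(s1), n_ind, length(keep_ind))

  masked <- geno[s1, keep_ind, drop = FALSE]
  dp <- depth[s1, keep_ind, drop = FALSE]
  for (a in seq_len(nrow(masked))) for (b in seq_len(ncol(masked))) {
    if (dp[a, b] < p$min_dp) masked[a, b] <- NA
  }
  log$min_depth <- c(length(s1), length(s1),
                     length(keep_ind), length(keep_ind))

  s2 <- integer(0)
  for (a in seq_along(s1)) {
    g <- masked[a, ]
    called <- sum(!is.na(g))
    if (called / length(keep_ind) < p$stage2_max_missing) next
    alt <- sum(g, na.rm = TRUE)
    total <- 2 * called
    maf <- if (total > 0) min(alt, total - alt) / total else 0
    if (maf < p$maf_min) next
    if (nall[s1[a]] > p$max_alleles) next
    s2 <- c(s2, s1[a])
  }
  log$stage2_sites <- c(length(s1), length(s2),
                        length(keep_ind), length(keep_ind))
  list(log = log, survivors = s2, individuals = keep_ind)
}

# Weir & Cockerham (1984) theta, ratio-of-averages, for diploid genotype
# dosage matrices split by population label. Test-side oracle only.
wc_theta <- function(geno, pops) {
  labs <- unique(pops)
  r <- length(labs)
  num <- den <- 0
  for (l in seq_len(nrow(geno))) {
    n_i <- p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      g <- geno[l, pops == labs[k]]
      g <- g[!is.na(g)]
      n_i[k] <- length(g)
      if (n_i[k] == 0) next
      p_i[k] <- sum(g) / (2 * n_i[k])
      h_i[k] <- mean(g == 1)
    }
    if (any(n_i == 0)) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    if (pbar == 0 || pbar == 1) next
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Balding-Nichols genotypes for a given station design, used by the
# AMOVA-vs-Fst property tests.
bn_genotypes <- function(n_per_group, n_groups, n_loci, fst) {
  n <- n_per_group * n_groups
  pops <- rep(seq_len(n_groups), each = n_per_group)
  p0 <- runif(n_loci, 0.1, 0.9)
  geno <- matrix(0L, n_loci, n)
  for (k in seq_len(n_groups)) {
    p <- if (fst == 0) p0 else
      rbeta(n_loci, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
    idx <- which(pops == k)
    geno[, idx] <- rbinom(n_loci * length(idx), 2L, p)
  }
  list(vm = make_vm(geno), pops = pops)
}

# NB count matrix with optional planted two-fold blocks, for DE tests.
nb_counts <- function(n_genes, group_sizes, mu = 100, alpha = 0.2,
                      planted = NULL) {
  n <- sum(group_sizes)
  m <- matrix(mu, n_genes, n)
  if (!is.null(planted)) {
    for (b in planted) m[b$genes, b$samples] <- mu * 2^b$lfc
  }
  counts <- matrix(rnbinom(n_genes * n, mu = m, size = 1 / alpha), n_genes,
                   dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                                   sprintf("s%02d", seq_len(n))))
  counts
}
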