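#' Hard-filter parameters for the SNP cascade
#'
#' Defaults reproduce the standard two-stage VCFtools-style cascade: site
#' Phred quality >= 30; stage 1 keeps loci genotyped in >= 50% of
#' individuals with minor allele count >= 3; individuals with more than 27%
#' missing data are dropped; stage 2 masks genotypes below 10 reads, then
#' keeps loci genotyped in >= 95% of individuals with minor allele frequency
#' >= 0.05 and at most 2 alleles.
#'
#' @param min_qual Phred site-quality threshold (sites strictly below are
#'   excluded).
#' @param stage1_max_missing,stage2_max_missing minimum fraction of
#'   individuals genotyped at a locus (VCFtools `--max-missing` semantics).
#' @param mac_min minimum minor allele count (stage 1), or `NULL` to skip.
#' @param indiv_max_missing individuals with missing fraction strictly above
#'   this are removed.
#' @param maf_min minimum minor allele frequency (stage 2), or `NULL`.
#' @param min_dp genotypes with depth below this are masked to missing.
#' @param max_alleles maximum number of alleles (REF + ALTs), or `NULL`.
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_qual = 30, stage1_max_missing = 0.5,
                          mac_min = 3, indiv_max_missing = 0.27,
                          stage2_max_missing = 0.95, maf_min = 0.05,
                          min_dp = 10, max_alleles = 2) {
  p <- list(min_qual = min_qual, stage1_max_missing = stage1_max_missing,
            mac_min = mac_min, indiv_max_missing = indiv_max_missing,
            stage2_max_missing = stage2_max_missing, maf_min = maf_min,
            min_dp = min_dp, max_alleles = max_alleles)
  stopifnot(p$min_qual >= 0, p$min_dp >= 0,
            p$stage1_max_missing >= 0, p$stage1_max_missing <= 1,
            p$stage2_max_missing >= 0, p$stage2_max_missing <= 1,
            p$indiv_max_missing >= 0, p$indiv_max_missing <= 1)
  structure(p, class = "filter_params")
}

#' Filter loci on Phred site quality
#'
#' Retains loci whose site quality is at least `min_qual` (quality strictly
#' below the threshold is excluded); locus order is preserved.
#'
#' @param v a [variant_matrix()].
#' @param min_qual Phred threshold.
#' @return Filtered [variant_matrix()].
#' @export
filter_site_quality <- function(v, min_qual) {
  stopifnot(min_qual >= 0)
  subset_loci(v, v$loci$qual >= min_qual)
}

#' Mask low-depth genotypes
#'
#' Sets genotype cells with read depth below `min_dp` to missing
#' (per-genotype masking, VCFtools `--minDP` semantics); no locus is
#' removed.
#'
#' @param v a [variant_matrix()].
#' @param min_dp minimum depth.
#' @return [variant_matrix()] with masked cells.
#' @export
apply_min_depth <- function(v, min_dp) {
  stopifnot(min_dp >= 0)
  v$geno[v$depth < min_dp] <- NA_integer_
  v
}

# Per-locus genotyping stats over non-missing genotypes.
locus_stats <- function(v) {
  n_called <- rowSums(!is.na(v$geno))
  alt <- rowSums(v$geno, na.rm = TRUE)
  total <- 2 * n_called
  minor <- pmin(alt, total - alt)
  list(called_frac = n_called / n_indiv(v),
       mac = minor,
       maf = ifelse(total > 0, minor / total, 0))
}

#' Site-level filters: missingness, MAC, MAF, allele number
#'
#' Retains loci genotyped in at least `max_missing` of individuals, with
#' minor allele count and frequency (computed over non-missing genotypes
#' only) meeting the thresholds, and with at most `max_alleles` alleles.
#' A frequency of exactly 0.5 counts as minor (MAF = 0.5). Passing `NULL`
#' skips a criterion.
#'
#' @param v a [variant_matrix()].
#' @param max_missing minimum fraction of individuals genotyped.
#' @param mac_min,maf_min,max_alleles optional thresholds.
#' @return Filtered [variant_matrix()].
#' @export
filter_sites <- function(v, max_missing, mac_min = NULL, maf_min = NULL,
                         max_alleles = NULL) {
  if (n_loci(v) == 0) return(v)
  st <- locus_stats(v)
  keep <- st$called_frac >= max_missing
  if (!is.null(mac_min)) keep <- keep & st$mac >= mac_min
  if (!is.null(maf_min)) keep <- keep & st$maf >= maf_min
  if (!is.null(max_alleles)) keep <- keep & v$loci$n_alleles <= max_alleles
  subset_loci(v, keep)
}

#' Drop individuals with excess missing data
#'
#' Removes individuals whose missing-genotype fraction over the current loci
#' is strictly greater than `indiv_max_missing` ("more than" semantics; a
#' fraction exactly at the threshold is retained).
#'
#' @param v a [variant_matrix()].
#' @param indiv_max_missing fraction in \[0,1\].
#' @return list with `v` (filtered matrix) and `removed` (identifiers).
#' @export
drop_high_missing_individuals <- function(v, indiv_max_missing) {
  stopifnot(indiv_max_missing >= 0, indiv_max_missing <= 1)
  if (n_loci(v) == 0) return(list(v = v, removed = character(0)))
  miss_frac <- colMeans(is.na(v$geno))
  drop <- miss_frac > indiv_max_missing
  if (all(drop)) stop("all individuals exceed the missingness threshold")
  list(v = subset_indiv(v, !drop), removed = v$samples[drop])
}

#' Partition loci into mitochondrial and nuclear compartments
#'
#' Loci on contigs labelled mitochondrial in the table go to the mito
#' matrix; every other locus — including loci on contigs absent from the
#' table — is treated as nuclear (the no-hit-means-nuclear rule).
#'
#' @param v a [variant_matrix()].
#' @param compartments data.frame `contig_id`, `compartment`.
#' @return list with `mito` and `nuclear` [variant_matrix()]s.
#' @export
partition_compartments <- function(v, compartments) {
  mito_contigs <- compartments$contig_id[
    compartments$compartment == "mitochondrial"]
  is_mito <- v$loci$contig %in% mito_contigs
  mito <- subset_loci(v, is_mito)
  nuclear <- subset_loci(v, !is_mito)
  if (n_loci(mito) > 0) mito$compartment[] <- "mitochondrial"
  if (n_loci(nuclear) > 0) nuclear$compartment[] <- "nuclear"
  list(mito = mito, nuclear = nuclear)
}

#' Run the full iterative filter cascade
#'
#' Fixed stage order: site quality; stage-1 site filter (missingness + MAC);
#' individual drop; minimum-depth masking; stage-2 site filter (missingness
#' + MAF + max-alleles). Depth masking sits immediately before the stage-2
#' site predicates, so stage-1 MAC is computed on unmasked genotypes. Every
#' stage is logged with loci/individual counts in and out.
#'
#' @param v a [variant_matrix()].
#' @param params a [filter_params()].
#' @return list with `v` (filtered matrix), `log` (data.frame funnel:
#'   stage, loci_in, loci_out, indiv_in, indiv_out) and
#'   `removed_individuals`.
#' @export
run_filter_cascade <- function(v, params = filter_params()) {
  log <- data.frame(stage = character(0), loci_in = integer(0),
                    loci_out = integer(0), indiv_in = integer(0),
                    indiv_out = integer(0), stringsAsFactors = FALSE)
  step <- function(name, v_in, v_out) {
    log[nrow(log) + 1L, ] <<- list(name, n_loci(v_in), n_loci(v_out),
                                   n_indiv(v_in), n_indiv(v_out))
    v_out
  }
  v1 <- step("site_quality", v, filter_site_quality(v, params$min_qual))
  v2 <- step("stage1_sites", v1,
             filter_sites(v1, params$stage1_max_missing,
                          mac_min = params$mac_min))
  dropped <- if (n_indiv(v2) > 0 && n_loci(v2) > 0) {
    drop_high_missing_individuals(v2, params$indiv_max_missing)
  } else list(v = v2, removed = character(0))
  v3 <- step("individuals", v2, dropped$v)
  v4 <- step("min_depth", v3, apply_min_depth(v3, params$min_dp))
  v5 <- step("stage2_sites", v4,
             filter_sites(v4, params$stage2_max_missing,
                          maf_min = params$maf_min,
                          max_alleles = params$max_alleles))
  list(v = v5, log = log, removed_individuals = dropped$removed)
}
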