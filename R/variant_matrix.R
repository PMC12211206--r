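#' Construct a variant matrix
#'
#' The central genotype container of the pipeline: loci in rows, individuals
#' in columns, with per-site Phred quality, per-genotype read depth and a
#' per-locus compartment label (mitochondrial / nuclear / unassigned).
#' Genotype dosages count ALT alleles: 0, 1, 2, or `NA` for a missing call.
#' Multi-allelic records are kept (dosage counted against the first ALT) with
#' their allele number recorded, so that a downstream max-alleles filter can
#' remove them.
#'
#' @param loci data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `n_alleles`, `qual` (Phred site quality).
#' @param geno integer matrix, loci x individuals, values in \{0,1,2,NA\}.
#' @param depth non-negative integer matrix, same shape as `geno`.
#' @param samples character vector of individual identifiers.
#' @param compartment per-locus label in
#'   \{"mitochondrial","nuclear","unassigned"\}; defaults to "unassigned".
#' @return An object of class `variant_matrix`.
#' @export
variant_matrix <- function(loci, geno, depth, samples,
                           compartment = rep("unassigned", nrow(loci))) {
  geno <- as.matrix(geno)
  depth <- as.matrix(depth)
  stopifnot(
    is.data.frame(loci),
    all(c("contig", "pos", "ref", "alt", "n_alleles", "qual") %in% names(loci)),
    nrow(geno) == nrow(loci), nrow(depth) == nrow(loci),
    ncol(geno) == length(samples), ncol(depth) == length(samples),
    length(compartment) == nrow(loci)
  )
  if (nrow(loci) > 0) {
    stopifnot(all(loci$pos >= 1), all(loci$qual >= 0))
    bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
    if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  }
  rownames(geno) <- rownames(depth) <- NULL
  colnames(geno) <- colnames(depth) <- samples
  structure(
    list(loci = loci, geno = geno, depth = depth,
         samples = samples, compartment = compartment),
    class = "variant_matrix"
  )
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d loci x %d individuals\n",
              n_loci(x), n_indiv(x)))
  tab <- table(factor(x$compartment,
                      levels = c("mitochondrial", "nuclear", "unassigned")))
  cat(sprintf("  compartments: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Number of loci / individuals in a variant matrix
#' @param v a `variant_matrix`
#' @return integer count
#' @export
n_loci <- function(v) nrow(v$loci)

#' @rdname n_loci
#' @export
n_indiv <- function(v) length(v$samples)

# Row/column subsetting that keeps all slots aligned.
subset_loci <- function(v, keep) {
  variant_matrix(v$loci[keep, , drop = FALSE],
                 v$geno[keep, , drop = FALSE],
                 v$depth[keep, , drop = FALSE],
                 v$samples,
                 v$compartment[keep])
}

subset_indiv <- function(v, keep) {
  variant_matrix(v$loci,
                 v$geno[, keep, drop = FALSE],
                 v$depth[, keep, drop = FALSE],
                 v$samples[keep],
                 v$compartment)
}

#' Read a VCF file into a variant matrix
#'
#' Parses a VCF v4.x file (uncompressed or gzipped). Missing genotypes
#' (`./.` or `.`) become `NA` dosages, the `QUAL` column becomes the per-site
#' Phred score, and the `DP` FORMAT field becomes per-genotype depth (0 when
#' absent). Multi-allelic records are retained; their dosage counts copies of
#' the first ALT allele and `n_alleles` records REF plus all ALTs so that the
#' max-alleles filter can act on them later.
#'
#' @param path path to a VCF file.
#' @return A [variant_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samples <- colnames(vcf@gt)[-1]
    if (is.null(samples)) samples <- character(0)
    empty <- data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        n_alleles = integer(0), qual = numeric(0),
                        stringsAsFactors = FALSE)
    m <- matrix(integer(0), nrow = 0, ncol = length(samples))
    return(variant_matrix(empty, m, m, samples))
  }
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  if (anyNA(qual)) stop("non-numeric QUAL in VCF: ", path)
  n_alleles <- 1L + lengths(strsplit(fix$ALT, ",", fixed = TRUE))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  samples <- colnames(gt)
  # dosage = number of '1' alleles (vs the first ALT) in the GT call
  dose_of <- function(calls) {
    out <- rep(NA_integer_, length(calls))
    ok <- !is.na(calls) & !grepl("\\.", calls)
    alleles <- strsplit(calls[ok], "[/|]")
    out[ok] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
    out
  }
  geno <- matrix(dose_of(as.vector(gt)), nrow = nrow(gt))
  dp[is.na(dp)] <- 0
  loci <- data.frame(contig = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     n_alleles = n_alleles, qual = qual,
                     stringsAsFactors = FALSE)
  variant_matrix(loci, geno, matrix(as.integer(dp), nrow = nrow(gt)), samples)
}

#' Write a variant matrix to a VCF file
#'
#' Emits a minimal VCF v4.2 with `GT:DP` FORMAT fields. Dosage 0/1/2 is
#' written as `0/0`, `0/1`, `1/1`; `NA` as `./.`.
#'
#' @param v a [variant_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=degnull",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", v$samples), collapse = "\t")
  ), con)
  if (n_loci(v) == 0) return(invisible(path))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = n_loci(v), ncol = n_indiv(v))
  idx <- !is.na(v$geno)
  gt[idx] <- gt_code[as.character(v$geno[idx])]
  cells <- matrix(paste0(gt, ":", v$depth), nrow = n_loci(v))
  lines <- paste(v$loci$contig, v$loci$pos, ".", v$loci$ref, v$loci$alt,
                 format(v$loci$qual, trim = TRUE, digits = 10), "PASS", ".",
                 "GT:DP", apply(cells, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
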