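#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the study design the downstream analyses assume: 15 expression samples
#' grouped by station (5/5/5), mitotype (2/7/3/3: homoplasmic h1h1 and h2h2,
#' heteroplasmic h1h3 and h2h3) and nuclear type (10/5), embedded in a
#' 27-individual genotyped cohort with weak nuclear station structure and a
#' strong mitochondrial h1-vs-h2 split.
#'
#' @param n_genes number of genes in the count matrix.
#' @param group_design named list: grouping name -> named integer vector of
#'   group sizes for the expression cohort. All groupings must sum to the
#'   same sample total.
#' @param geno_extra_design like `group_design`, sizes of the *additional*
#'   genotype-only individuals per group (the genotyped cohort is the
#'   expression cohort plus these). Same grouping names required.
#' @param de_fraction fraction of genes planted as differentially expressed
#'   per contrast, in \[0,1).
#' @param effect_log2fc planted absolute log2 fold change.
#' @param dispersion negative-binomial dispersion alpha (Var = mu + alpha mu^2).
#' @param libsize_range (min, max) of library-size factors; sizes are drawn
#'   log-uniformly over this range.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline expression on
#'   the count scale.
#' @param n_loci_nuclear,n_loci_mito numbers of simulated nuclear and
#'   mitochondrial loci.
#' @param fst_nuclear planted Balding-Nichols differentiation between
#'   stations at nuclear loci, in \[0,1).
#' @param mito_divergence fraction of mitochondrial loci at which the h1 and
#'   h2 haplotype clusters carry different alleles.
#' @param het_admix fraction of divergent mitochondrial loci at which a
#'   heteroplasmic individual shows an intermediate dosage (minor-haplotype
#'   admixture).
#' @param missing_rate per-genotype missingness probability.
#' @param depth_mean mean per-genotype read depth (Poisson).
#' @param qual_range (min, max) of uniform per-site Phred quality.
#' @param seed integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       group_design = list(
                         station = c(Base = 5, Glacier = 5, Faro = 5),
                         mitotype = c(h1h1 = 2, h2h2 = 7, h1h3 = 3, h2h3 = 3),
                         nuclear_type = c(NucA = 10, NucB = 5)),
                       geno_extra_design = list(
                         station = c(Base = 4, Glacier = 4, Faro = 4),
                         mitotype = c(h1h1 = 2, h2h2 = 6, h1h3 = 2, h2h3 = 2),
                         nuclear_type = c(NucA = 8, NucB = 4)),
                       de_fraction = 0.05,
                       effect_log2fc = 2,
                       dispersion = 0.2,
                       libsize_range = c(0.5, 2),
                       baseline_meanlog = 4,
                       baseline_sdlog = 1,
                       n_loci_nuclear = 2000,
                       n_loci_mito = 145,
                       fst_nuclear = 0.03,
                       mito_divergence = 0.8,
                       het_admix = 0.25,
                       missing_rate = 0.05,
                       depth_mean = 20,
                       qual_range = c(20, 60),
                       seed = 1) {
  cfg <- list(n_genes = n_genes, group_design = group_design,
              geno_extra_design = geno_extra_design,
              de_fraction = de_fraction, effect_log2fc = effect_log2fc,
              dispersion = dispersion, libsize_range = libsize_range,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              n_loci_nuclear = n_loci_nuclear, n_loci_mito = n_loci_mito,
              fst_nuclear = fst_nuclear, mito_divergence = mito_divergence,
              het_admix = het_admix, missing_rate = missing_rate,
              depth_mean = depth_mean, qual_range = qual_range, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1,
            cfg$de_fraction >= 0, cfg$de_fraction < 1,
            cfg$effect_log2fc > 0, cfg$dispersion > 0,
            length(cfg$libsize_range) == 2, all(cfg$libsize_range > 0),
            cfg$n_loci_nuclear >= 1, cfg$n_loci_mito >= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$depth_mean > 0)
  if (cfg$fst_nuclear < 0 || cfg$fst_nuclear >= 1)
    stop("fst_nuclear must lie in [0, 1)")
  check_design <- function(design, what) {
    if (length(design) == 0) stop("empty ", what)
    totals <- vapply(design, sum, numeric(1))
    if (any(vapply(design, function(s) any(s <= 0) && length(s) > 0,
                   logical(1))) && what == "group_design")
      stop("group sizes must be positive in ", what)
    if (length(unique(totals)) != 1) {
      bad <- names(totals)[c(1, which(totals != totals[1])[1])]
      stop(sprintf(
        "inconsistent sample totals across groupings '%s' (%d) and '%s' (%d)",
        bad[1], totals[bad[1]], bad[2], totals[bad[2]]))
    }
    totals[1]
  }
  check_design(cfg$group_design, "group_design")
  if (!identical(sort(names(cfg$group_design)),
                 sort(names(cfg$geno_extra_design))))
    stop("group_design and geno_extra_design must share grouping names")
  check_design(cfg$geno_extra_design, "geno_extra_design")
  invisible(cfg)
}

#' Simulate sample metadata
#'
#' Builds the sample table: one row per individual, one column per grouping,
#' each grouping holding exactly the configured number of samples per label.
#' The expression cohort (`in_expression = TRUE`) comes first; the remaining
#' rows are genotype-only individuals. Label-to-sample assignment within a
#' cohort is randomized so the groupings are not trivially nested.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `sample_id`, one per grouping, and
#'   `in_expression`.
#' @export
simulate_metadata <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_expr <- sum(config$group_design[[1]])
  n_extra <- sum(config$geno_extra_design[[1]])
  n_tot <- n_expr + n_extra
  ids <- sprintf("S%02d", seq_len(n_tot))
  meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (gname in names(config$group_design)) {
    sizes <- config$group_design[[gname]]
    extra <- config$geno_extra_design[[gname]]
    expr_labels <- sample(rep(names(sizes), times = sizes))
    extra_labels <- if (n_extra > 0) {
      sample(rep(names(extra), times = extra))
    } else character(0)
    meta[[gname]] <- c(expr_labels, extra_labels)
  }
  meta$in_expression <- c(rep(TRUE, n_expr), rep(FALSE, n_extra))
  meta
}

# One planted contrast per grouping. Mitotype designs carrying both
# heteroplasmic labels get the homoplasmic-vs-heteroplasmic split (the
# dominant expression pattern in this system); any other grouping uses its
# first label vs all others pooled.
truth_contrasts <- function(config) {
  lapply(config$group_design, function(sizes) {
    labels <- names(sizes)
    het <- c("h1h3", "h2h3")
    if (all(het %in% labels)) {
      list(focal = het, rest = setdiff(labels, het))
    } else {
      list(focal = labels[1], rest = labels[-1])
    }
  })
}

#' Simulate an expression count matrix with planted group effects
#'
#' Draws raw counts from a negative-binomial model
#' `K ~ NB(mean = baseline * libsize * 2^(+/- effect), dispersion alpha)`.
#' For each grouping, one contrast (first group label vs the rest) receives
#' `de_fraction * n_genes` planted genes with a signed log2 fold change of
#' `effect_log2fc`; the returned truth set records them.
#'
#' @param config a [sim_config()].
#' @param metadata output of [simulate_metadata()] (only rows with
#'   `in_expression = TRUE` receive counts).
#' @return list with `counts` (integer matrix, genes x samples, gene ids as
#'   rownames) and `truth` (per-grouping list of `gene_id`/`log2fc`
#'   data.frames plus `mitotype_assignment`).
#' @export
simulate_counts <- function(config, metadata) {
  validate_sim_config(config)
  n_planted <- round(config$de_fraction * config$n_genes)
  if (n_planted > config$n_genes)
    stop("de_fraction * n_genes exceeds n_genes")
  set.seed(config$seed + 1L)
  meta <- metadata[metadata$in_expression, , drop = FALSE]
  n_s <- nrow(meta)
  gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
  baseline <- stats::rlnorm(config$n_genes,
                            config$baseline_meanlog, config$baseline_sdlog)
  lib <- exp(stats::runif(n_s, log(config$libsize_range[1]),
                          log(config$libsize_range[2])))
  log2_shift <- matrix(0, config$n_genes, n_s)
  truth <- list()
  for (gname in names(config$group_design)) {
    contrast <- truth_contrasts(config)[[gname]]
    if (n_planted == 0) {
      truth[[gname]] <- data.frame(gene_id = character(0),
                                   log2fc = numeric(0),
                                   stringsAsFactors = FALSE)
      next
    }
    planted <- sort(sample.int(config$n_genes, n_planted))
    sign <- sample(c(-1, 1), n_planted, replace = TRUE)
    lfc <- sign * config$effect_log2fc
    in_focal <- meta[[gname]] %in% contrast$focal
    # focal group shifted by the full planted log2FC relative to the rest
    log2_shift[planted, in_focal] <- log2_shift[planted, in_focal] + lfc
    truth[[gname]] <- data.frame(gene_id = gene_ids[planted], log2fc = lfc,
                                 stringsAsFactors = FALSE)
  }
  mu <- baseline * t(lib * t(2^log2_shift))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$dispersion),
                   nrow = config$n_genes,
                   dimnames = list(gene_ids, meta$sample_id))
  mt <- if ("mitotype" %in% names(metadata)) {
    as.list(stats::setNames(metadata$mitotype, metadata$sample_id))
  } else list()
  list(counts = counts,
       truth = list(de_genes = truth,
                    contrasts = truth_contrasts(config),
                    mitotype_assignment = mt))
}

#' Simulate a genotype matrix as a variant matrix
#'
#' Nuclear loci follow a Balding-Nichols model: an ancestral allele
#' frequency per locus, per-station frequencies drawn
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` at `F = fst_nuclear`, diploid dosages
#' binomial. Mitochondrial loci are effectively clonal: the h1-carrying
#' cluster (h1h1, h1h3) and the h2-carrying cluster (h2h2, h2h3) differ at
#' `mito_divergence` of mito loci (dosage 0 vs 2), and heteroplasmic
#' individuals show intermediate dosage 1 at a `het_admix` fraction of those
#' divergent loci, mimicking minor-haplotype admixture. Per-site Phred
#' quality is uniform over `qual_range`, per-genotype depth Poisson, and
#' genotypes go missing independently at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @param metadata output of [simulate_metadata()]; all rows are genotyped.
#' @return A [variant_matrix()] (mito loci first, on contig `"contig_mito"`;
#'   nuclear loci spread over contigs of ~10 loci each).
#' @export
simulate_genotypes <- function(config, metadata) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(metadata)
  Ln <- config$n_loci_nuclear
  Lm <- config$n_loci_mito
  F <- config$fst_nuclear

  station <- metadata$station
  stations <- unique(station)
  p0 <- stats::runif(Ln, 0.1, 0.9)
  geno_nuc <- matrix(0L, Ln, n)
  for (st in stations) {
    p_st <- if (F == 0) p0 else
      stats::rbeta(Ln, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    idx <- which(station == st)
    geno_nuc[, idx] <- stats::rbinom(Ln * length(idx), 2L, p_st)
  }

  h1_cluster <- metadata$mitotype %in% c("h1h1", "h1h3")
  heteroplasmic <- metadata$mitotype %in% c("h1h3", "h2h3")
  divergent <- stats::runif(Lm) < config$mito_divergence
  geno_mito <- matrix(0L, Lm, n)
  geno_mito[divergent, !h1_cluster] <- 2L
  for (j in which(heteroplasmic)) {
    admix <- which(divergent)[stats::runif(sum(divergent)) < config$het_admix]
    geno_mito[admix, j] <- 1L
  }

  geno <- rbind(geno_mito, geno_nuc)
  L <- Lm + Ln
  contig <- c(rep("contig_mito", Lm),
              sprintf("contig%05d", (seq_len(Ln) - 1) %/% 10 + 1))
  pos <- c(seq_len(Lm) * 100L,
           as.integer((seq_len(Ln) - 1) %% 10 + 1) * 150L)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  qual <- stats::runif(L, config$qual_range[1], config$qual_range[2])
  depth <- matrix(stats::rpois(L * n, config$depth_mean), L, n)
  if (config$missing_rate > 0) {
    geno[stats::runif(L * n) < config$missing_rate] <- NA_integer_
  }
  loci <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                     n_alleles = 2L, qual = qual, stringsAsFactors = FALSE)
  variant_matrix(loci, geno, depth, metadata$sample_id)
}

#' Contig-compartment table for a simulated variant matrix
#'
#' @param v a [variant_matrix()] from [simulate_genotypes()].
#' @return data.frame `contig_id`, `compartment` (the mito contig labelled
#'   mitochondrial, all others nuclear).
#' @export
compartment_table <- function(v) {
  contigs <- unique(v$loci$contig)
  data.frame(contig_id = contigs,
             compartment = ifelse(contigs == "contig_mito",
                                  "mitochondrial", "nuclear"),
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits the full set of analysis inputs — counts TSV, metadata TSV, VCF,
#' contig-compartment TSV, truth JSON — plus a manifest recording files and
#' seed. Everything round-trips losslessly through the module readers.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if absent).
#' @return The manifest as a list (`files`, `seed`), invisibly written to
#'   `manifest.json` as well.
#' @export
write_fixture_set <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  meta <- simulate_metadata(config)
  sim <- simulate_counts(config, meta)
  v <- simulate_genotypes(config, meta)

  paths <- list(
    counts = file.path(outdir, "counts.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    vcf = file.path(outdir, "genotypes.vcf"),
    compartments = file.path(outdir, "compartments.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_counts(sim$counts, paths$counts)
  utils::write.table(meta, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_vcf(v, paths$vcf)
  utils::write.table(compartment_table(v), paths$compartments, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE, digits = NA)

  manifest <- list(files = lapply(paths, basename), seed = config$seed)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  manifest
}

#' Read / write a counts TSV (first column `gene_id`, then sample columns)
#' @param path TSV path.
#' @return integer matrix, genes x samples, gene ids as rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_counts
#' @param counts integer matrix with gene-id rownames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata TSV
#' @param path TSV with columns `sample_id`, `station`, `mitotype`,
#'   `nuclear_type` (and optionally `in_expression`).
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(meta))
  meta
}

#' Read a contig-compartment TSV
#' @param path TSV with columns `contig_id`, `compartment`.
#' @return data.frame.
#' @export
read_compartments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "compartment") %in% names(df)))
  df
}
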