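#' Pipeline configuration
#'
#' Describes a full analysis run: where the inputs come from (a simulation
#' config or file paths), the filter parameters, the DE thresholds, which
#' metadata groupings to analyze, and the iteration counts and seeds of the
#' stochastic stages.
#'
#' @param sim a [sim_config()] to generate inputs in memory, or `NULL` when
#'   reading from files.
#' @param paths named list with `counts`, `metadata`, `vcf`, `compartments`
#'   (used when `sim` is `NULL`).
#' @param filter a [filter_params()].
#' @param thresholds a [de_thresholds()].
#' @param groupings metadata columns to run DE + randomization on.
#' @param n_iter randomized analyses per grouping.
#' @param n_perm AMOVA permutations.
#' @param n_boot bootstrap resamples for the Q0.95 interval.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            filter = filter_params(),
                            thresholds = de_thresholds(),
                            groupings = c("station", "mitotype",
                                          "nuclear_type"),
                            n_iter = 1000, n_perm = 1000, n_boot = 1000,
                            seed = 1) {
  if (is.null(sim) && is.null(paths))
    stop("either a simulation config or input paths must be given")
  structure(list(sim = sim, paths = paths, filter = filter,
                 thresholds = thresholds, groupings = groupings,
                 n_iter = n_iter, n_perm = n_perm, n_boot = n_boot,
                 seed = seed),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$sim)) {
    meta <- simulate_metadata(config$sim)
    sim <- simulate_counts(config$sim, meta)
    v <- simulate_genotypes(config$sim, meta)
    list(counts = sim$counts, meta = meta, v = v,
         compartments = compartment_table(v), truth = sim$truth)
  } else {
    p <- config$paths
    list(counts = read_counts(p$counts), meta = read_metadata(p$metadata),
         v = read_vcf(p$vcf), compartments = read_compartments(p$compartments),
         truth = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate inputs; SNP filter cascade;
#' mitochondrial/nuclear partition; per-compartment AMOVA (between
#' stations, permutation significance), genotype PCA and pairwise station
#' G'ST; per-grouping pairwise differential expression on the expression
#' subset; per-grouping randomization null, gamma-family fit, Q0.95 with
#' bootstrap interval, and exceedance verdict. Fully deterministic given
#' the configuration (all stage seeds derive from `config$seed`).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return A `pipeline_report` list: `filter_log`, `amova`, `pca`, `gst`,
#'   `de` (per grouping: per-pair counts, union count, null fit summary,
#'   verdict), `provenance`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  inputs <- load_pipeline_inputs(config)
  meta <- inputs$meta
  missing_cols <- setdiff(config$groupings, names(meta))
  if (length(missing_cols) > 0)
    stop("grouping column(s) absent from metadata: ",
         paste(missing_cols, collapse = ", "))
  expr_meta <- if ("in_expression" %in% names(meta)) {
    meta[meta$in_expression, , drop = FALSE]
  } else meta
  if (!all(colnames(inputs$counts) %in% meta$sample_id))
    stop("count-matrix samples missing from metadata")

  say("stage filter: %d loci x %d individuals in",
      n_loci(inputs$v), n_indiv(inputs$v))
  filt <- run_filter_cascade(inputs$v, config$filter)
  say("stage filter: %d loci x %d individuals out",
      n_loci(filt$v), n_indiv(filt$v))
  parts <- partition_compartments(filt$v, inputs$compartments)

  geno_meta <- meta[match(filt$v$samples, meta$sample_id), , drop = FALSE]
  structure_res <- list()
  for (comp in c("mito", "nuclear")) {
    v <- parts[[comp]]
    if (n_loci(v) == 0 || n_indiv(v) < 3) {
      say("stage structure: skipping %s (too little data)", comp)
      next
    }
    say("stage structure: %s (%d loci)", comp, n_loci(v))
    d2 <- pairwise_distance_matrix(v)
    am <- amova_permutation_test(d2, geno_meta$station,
                                 n_perm = config$n_perm,
                                 seed = config$seed + 101)
    pca <- genotype_pca(v, n_components = 2)
    stations <- unique(geno_meta$station)
    gst <- list()
    for (i in seq_along(stations)[-length(stations)]) {
      for (j in seq((i + 1), length(stations))) {
        pair <- c(stations[i], stations[j])
        g <- tryCatch(hedrick_gst_pairwise(v, geno_meta$station, pair),
                      error = function(e) NULL)
        if (!is.null(g))
          gst[[paste(pair, collapse = "_vs_")]] <-
            list(pair = pair, mean_gst = g$mean_gst,
                 n_loci_used = g$n_loci_used)
      }
    }
    structure_res[[comp]] <- list(
      amova = unclass(am),
      pca = list(explained_pct = pca$explained_pct[
        seq_len(min(5, length(pca$explained_pct)))]),
      gst = gst)
  }

  expr_counts <- inputs$counts[, expr_meta$sample_id, drop = FALSE]
  de_res <- list()
  for (gname in config$groupings) {
    say("stage de/null: grouping %s", gname)
    obs <- union_deg_count(expr_counts, expr_meta, gname, config$thresholds)
    sizes <- table(expr_meta[[gname]])
    conf <- size_conformation(as.integer(sizes), names(sizes))
    nulls <- null_distribution(expr_counts, colnames(expr_counts), conf,
                               config$thresholds, n_iter = config$n_iter,
                               seed = config$seed + 211 +
                                 match(gname, config$groupings))
    fit <- fit_null(nulls)
    ci <- gamma_q95_ci(fit, n_boot = config$n_boot,
                       seed = config$seed + 307)
    verdict <- exceedance_test(obs$union_count, fit)
    de_res[[gname]] <- list(
      conformation = as.integer(sizes),
      per_pair = as.list(obs$per_pair),
      union_count = obs$union_count,
      null = list(
        n_iter = fit$n_iter,
        selected = fit$selected$name,
        parameters = as.list(fit$selected$estimate),
        shift = fit$shift,
        aic = lapply(fit$candidate_fits, `[[`, "aic"),
        mean = mean(fit$values),
        q95 = fit$q95,
        q95_ci = ci$ci),
      verdict = unclass(verdict))
  }

  report <- list(
    filter_log = filt$log,
    removed_individuals = filt$removed_individuals,
    n_snps = list(total = n_loci(filt$v),
                  mito = n_loci(parts$mito),
                  nuclear = n_loci(parts$nuclear)),
    structure = structure_res,
    de = de_res,
    truth = if (!is.null(inputs$truth)) {
      lapply(inputs$truth$de_genes, nrow)
    } else NULL,
    provenance = list(
      package_version = as.character(utils::packageVersion("degnull")),
      seed = config$seed, n_iter = config$n_iter, n_perm = config$n_perm,
      config_hash = config_hash(config))
  )
  class(report) <- "pipeline_report"
  report
}

# md5 of the serialized configuration, for provenance.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Write a pipeline report to disk
#'
#' Emits the full report as JSON plus human-readable TSVs: the filter
#' funnel, an AMOVA table (rows "Between stations" / "Within individuals",
#' percentages floored at 0), per-pair DEG counts, null-fit summaries and
#' G'ST means.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param outdir output directory (created if absent).
#' @return named list of written paths.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(json = file.path(outdir, "report.json"),
                filter = file.path(outdir, "filter_funnel.tsv"),
                amova = file.path(outdir, "amova.tsv"),
                degs = file.path(outdir, "deg_counts.tsv"),
                nulls = file.path(outdir, "null_summary.tsv"),
                gst = file.path(outdir, "gst.tsv"))
  jsonlite::write_json(unclass(report), paths$json, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")
  utils::write.table(report$filter_log, paths$filter, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  amova_rows <- do.call(rbind, lapply(names(report$structure), function(comp) {
    a <- report$structure[[comp]]$amova
    among_disp <- max(a$pct_among, 0) # negative components floored here only
    data.frame(
      compartment = comp,
      source_of_variation = c("Between stations", "Within individuals"),
      df = c(a$df_among, a$df_within),
      sum_of_squares = c(a$ss_among, a$ss_within),
      pct_of_variation = c(among_disp, 100 - among_disp),
      p_value = c(a$p_value, NA),
      stringsAsFactors = FALSE)
  }))
  if (is.null(amova_rows))
    amova_rows <- data.frame(compartment = character(0),
                             source_of_variation = character(0),
                             df = integer(0), sum_of_squares = numeric(0),
                             pct_of_variation = numeric(0),
                             p_value = numeric(0))
  utils::write.table(amova_rows, paths$amova, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  deg_rows <- do.call(rbind, lapply(names(report$de), function(g) {
    d <- report$de[[g]]
    rbind(data.frame(grouping = g, comparison = names(d$per_pair),
                     degs = unlist(d$per_pair), stringsAsFactors = FALSE),
          data.frame(grouping = g, comparison = "union",
                     degs = d$union_count, stringsAsFactors = FALSE))
  }))
  utils::write.table(deg_rows, paths$degs, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  null_rows <- do.call(rbind, lapply(names(report$de), function(g) {
    d <- report$de[[g]]
    data.frame(grouping = g, observed = d$verdict$observed,
               null_mean = d$null$mean, selected = d$null$selected,
               q95 = d$null$q95, q95_lo = d$null$q95_ci[1],
               q95_hi = d$null$q95_ci[2], exceeds = d$verdict$exceeds,
               empirical_p = d$verdict$empirical_p,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(null_rows, paths$nulls, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  gst_rows <- do.call(rbind, lapply(names(report$structure), function(comp) {
    g <- report$structure[[comp]]$gst
    if (length(g) == 0) return(NULL)
    data.frame(compartment = comp, comparison = names(g),
               mean_gst = vapply(g, `[[`, numeric(1), "mean_gst"),
               n_loci_used = vapply(g, `[[`, numeric(1), "n_loci_used"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(gst_rows))
    gst_rows <- data.frame(compartment = character(0),
                           comparison = character(0),
                           mean_gst = numeric(0), n_loci_used = numeric(0))
  utils::write.table(gst_rows, paths$gst, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
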