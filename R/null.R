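#' Size conformation of a grouping
#'
#' The multiset of group sizes that randomized groupings must preserve,
#' e.g. `(5,5,5)` for three stations, `(2,7,3,3)` for the four mitotypes,
#' `(10,5)` for the two nuclear types.
#'
#' @param sizes positive integer vector of group sizes.
#' @param labels optional group labels (defaults `g1`, `g2`, ...).
#' @return A `size_conformation` list with `sizes`, `labels`, `total`.
#' @export
size_conformation <- function(sizes, labels = NULL) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 1, all(sizes > 0))
  if (is.null(labels)) labels <- paste0("g", seq_along(sizes))
  stopifnot(length(labels) == length(sizes))
  structure(list(sizes = sizes, labels = labels, total = sum(sizes)),
            class = "size_conformation")
}

#' Draw a uniformly random grouping of fixed size conformation
#'
#' Partitions the sample ids into labeled groups of exactly the stated
#' sizes, uniformly at random (every assignment of samples to the ordered
#' group slots is equally likely).
#'
#' @param sample_ids character vector; length must equal the conformation
#'   total.
#' @param conf a [size_conformation()].
#' @return named character vector: sample id -> group label.
#' @export
random_grouping <- function(sample_ids, conf) {
  if (length(sample_ids) != conf$total)
    stop(sprintf("got %d samples but conformation totals %d",
                 length(sample_ids), conf$total))
  labels <- rep(conf$labels, times = conf$sizes)
  stats::setNames(sample(labels), sample_ids)
}

#' Null distribution of DEG counts under randomized groupings
#'
#' The validation procedure's engine: repeatedly draws a random grouping
#' with the original size conformation, reruns the full pairwise
#' differential-expression analysis, and records the union DEG count.
#' Groupings are sampled independently across iterations (with replacement
#' over the partition space).
#'
#' @param counts integer matrix, genes x samples.
#' @param sample_ids samples to randomize over (default: all columns).
#' @param conf a [size_conformation()].
#' @param thresholds a [de_thresholds()].
#' @param n_iter number of randomized analyses.
#' @param seed RNG seed.
#' @return integer vector of `n_iter` union DEG counts.
#' @export
null_distribution <- function(counts, sample_ids = colnames(counts), conf,
                              thresholds = de_thresholds(),
                              n_iter = 1000, seed = 1) {
  stopifnot(n_iter >= 2)
  counts <- as.matrix(counts)[, sample_ids, drop = FALSE]
  prep <- de_prepare(counts)
  set.seed(seed)
  out <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    perm <- sample.int(conf$total)
    group_idx <- split(perm, rep(conf$labels, times = conf$sizes))[conf$labels]
    out[it] <- union_deg_count_prepared(prep, group_idx,
                                        thresholds)$union_count
  }
  out
}

# Families with positive support get the +0.5 shift when zeros are present.
.null_candidates <- c("gamma", "lnorm", "weibull", "norm")
.positive_support <- c(gamma = TRUE, lnorm = TRUE, weibull = TRUE,
                       norm = FALSE)

#' Fit candidate distributions to a null DEG-count sample
#'
#' Maximum-likelihood fits of the candidate set (gamma, lognormal, Weibull,
#' normal) with AIC-based model selection (`AIC = 2k - 2 logLik`). If any
#' value is <= 0, positive-support candidates are fitted on values shifted
#' by +0.5; the shift is recorded and undone when quantiles are computed.
#' The selected distribution's 0.95 quantile (`q95`) is evaluated
#' immediately; its confidence interval comes from [gamma_q95_ci()].
#'
#' @param values numeric vector of null DEG counts (>= 10 values).
#' @param candidates subset of `c("gamma","lnorm","weibull","norm")`.
#' @return object of class `null_fit`: `values`, `candidate_fits` (name,
#'   parameters, logLik, AIC), `selected`, `shift`, `q95`, `n_iter`.
#' @export
fit_null <- function(values, candidates = .null_candidates) {
  stopifnot(length(values) >= 10, all(is.finite(values)))
  candidates <- match.arg(candidates, .null_candidates, several.ok = TRUE)
  if (length(unique(values)) == 1)
    stop("degenerate null sample: all ", length(values),
         " values equal ", values[1])
  shift <- if (any(values <= 0)) 0.5 else 0
  fits <- list()
  for (name in candidates) {
    x <- if (.positive_support[[name]]) values + shift else values
    fit <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(x, name, method = "mle")),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$estimate)) next
    fits[[name]] <- list(name = name, estimate = fit$estimate,
                         logLik = as.numeric(stats::logLik(fit)),
                         aic = fit$aic)
  }
  if (length(fits) == 0) stop("no candidate distribution could be fitted")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  selected <- fits[[which.min(aics)]]
  fit <- structure(list(values = values, candidate_fits = fits,
                        selected = selected, shift = shift,
                        n_iter = length(values)),
                   class = "null_fit")
  fit$q95 <- null_quantile(fit, 0.95)
  fit
}

# Inverse CDF of the selected distribution on the original (unshifted)
# scale, floored at 0.
null_quantile <- function(fit, p) {
  est <- fit$selected$estimate
  name <- fit$selected$name
  qfun <- switch(name,
                 gamma = function(p) stats::qgamma(p, est[["shape"]],
                                                   rate = est[["rate"]]),
                 lnorm = function(p) stats::qlnorm(p, est[["meanlog"]],
                                                   est[["sdlog"]]),
                 weibull = function(p) stats::qweibull(p, est[["shape"]],
                                                       est[["scale"]]),
                 norm = function(p) stats::qnorm(p, est[["mean"]],
                                                 est[["sd"]]))
  q <- qfun(p)
  if (.positive_support[[name]]) q <- q - fit$shift
  max(q, 0)
}

#' Q0.95 of the fitted null with a parametric-bootstrap confidence interval
#'
#' The point estimate is the inverse CDF of the selected distribution at
#' 0.95. The interval comes from a parametric bootstrap: `n_boot` samples
#' of size `n_iter` are drawn from the fitted distribution, refitted within
#' the same family, and the percentile interval of the resampled quantiles
#' at `conf_level` is reported. Non-converged refits are skipped; more than
#' 10% skipped is an error.
#'
#' @param fit a `null_fit` from [fit_null()].
#' @param conf_level confidence level for the percentile interval.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed.
#' @return list with `q95` and `ci` (length-2 vector).
#' @export
gamma_q95_ci <- function(fit, conf_level = 0.95, n_boot = 1000, seed = 1) {
  est <- fit$selected$estimate
  name <- fit$selected$name
  rfun <- switch(name,
                 gamma = function(n) stats::rgamma(n, est[["shape"]],
                                                   rate = est[["rate"]]),
                 lnorm = function(n) stats::rlnorm(n, est[["meanlog"]],
                                                   est[["sdlog"]]),
                 weibull = function(n) stats::rweibull(n, est[["shape"]],
                                                       est[["scale"]]),
                 norm = function(n) stats::rnorm(n, est[["mean"]],
                                                 est[["sd"]]))
  set.seed(seed)
  qs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    x <- rfun(fit$n_iter)
    refit <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(x, name, method = "mle")),
      error = function(e) NULL)
    if (is.null(refit) || anyNA(refit$estimate)) next
    sub <- fit
    sub$selected <- list(name = name, estimate = refit$estimate)
    qs[b] <- null_quantile(sub, 0.95)
  }
  skipped <- mean(is.na(qs))
  if (skipped > 0.1)
    stop(sprintf("%.0f%% of bootstrap refits failed to converge",
                 100 * skipped))
  ci <- unname(stats::quantile(qs, c((1 - conf_level) / 2,
                                     1 - (1 - conf_level) / 2),
                               na.rm = TRUE))
  list(q95 = fit$q95, ci = ci)
}

#' Exceedance verdict: does the observed DEG count beat the null?
#'
#' `exceeds` is true iff the observed count is strictly greater than the
#' fitted Q0.95. An empirical permutation p-value
#' `(1 + #[null >= observed]) / (n_iter + 1)` is reported alongside as a
#' distribution-free check.
#'
#' @param observed observed union DEG count (integer).
#' @param fit a `null_fit` from [fit_null()].
#' @return list of class `exceedance_verdict`: `observed`, `q95`,
#'   `exceeds`, `empirical_p`.
#' @export
exceedance_test <- function(observed, fit) {
  stopifnot(is.finite(observed), !is.null(fit$q95))
  structure(list(observed = observed, q95 = fit$q95,
                 exceeds = observed > fit$q95,
                 empirical_p = (1 + sum(fit$values >= observed)) /
                   (fit$n_iter + 1)),
            class = "exceedance_verdict")
}
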