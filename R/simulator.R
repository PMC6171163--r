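## Monte-Carlo simulator: per-cohort minor-allele counts under a frequency
## specification, the five association Z-statistics per replicate, and
## empirical estimates of every analytic quantity (correlations,
## noncentralities, hit rates). Serves as the package's universal oracle
## and as the estimation path when analytic correlations do not apply
## (e.g. covariate-adjusted statistics).

#' Simulate per-cohort minor-allele counts
#'
#' Draws, for each replicate, the minor-allele count of each cohort as
#' `Binomial(2 n, mu)` (diploid Hardy-Weinberg sampling at the allele
#' level), independently across cohorts and replicates. This is the
#' minimal sampling law consistent with the variance model
#' `var(m) = mu (1 - mu) / (2 n)` underlying the analytic results.
#' A single seeded RNG stream makes the draw bit-reproducible.
#'
#' @param design A one-row design data frame.
#' @param spec A `repool_freqs` frequency specification.
#' @param n_rep Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return An object of class `repool_sim`: a list with `counts` (tibble
#'   of allele counts `m0`, `m1`, `m0p`, `m1p`), `design`, `spec`,
#'   `n_rep`, `seed`.
#' @examples
#' simulate_counts(study_design(500, 500, 500, 500),
#'                 frequency_spec(0.1, 0.1), n_rep = 10, seed = 1)
#' @export
simulate_counts <- function(design, spec, n_rep, seed) {
  d <- as_design(design)
  validate_freqs(spec)
  if (!is.numeric(n_rep) || n_rep < 1) stop("n_rep must be >= 1",
                                            call. = FALSE)
  n_rep <- as.integer(n_rep)
  # restore the caller's RNG state afterwards
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  counts <- tibble::tibble(
    m0  = stats::rbinom(n_rep, 2 * d$n0,  spec$mu0),
    m1  = stats::rbinom(n_rep, 2 * d$n1,  spec$mu1),
    m0p = stats::rbinom(n_rep, 2 * d$n0p, spec$mu0p),
    m1p = stats::rbinom(n_rep, 2 * d$n1p, spec$mu1p)
  )
  structure(
    list(counts = counts, design = tibble::as_tibble(d), spec = spec,
         n_rep = n_rep, seed = as.integer(seed)),
    class = "repool_sim"
  )
}

#' Per-replicate association Z-statistics
#'
#' Computes the five signed Z-statistics for every simulated replicate as
#' score-type two-proportion tests: the difference of the two compared
#' group allele-frequency estimates over the pooled-frequency null
#' standard error. Comparisons are discovery (`C1` vs `C0`), replication
#' (`C1'` vs `C0'`), shared replication (`C1'` vs `C0 u C0'`), pooled
#' discovery (`C1` vs `C0 u C0'`) and meta (`C1 u C1'` vs `C0 u C0'`).
#' Replicates in which any compared group is monomorphic (pooled count 0
#' or maximal) are excluded; the number excluded is attached as attribute
#' `n_excluded`.
#'
#' @param sim A `repool_sim` object.
#' @return A tibble with columns `z_d`, `z_r`, `z_s`, `z_c`, `z_m`, one
#'   row per retained replicate.
#' @export
statistics_from_counts <- function(sim) {
  stopifnot(inherits(sim, "repool_sim"))
  d <- as.list(sim$design)
  ct <- sim$counts
  two_prop_z <- function(ca, na2, cb, nb2) {
    fa <- ca / na2
    fb <- cb / nb2
    p <- (ca + cb) / (na2 + nb2)
    z <- (fa - fb) / sqrt(p * (1 - p) * (1 / na2 + 1 / nb2))
    z[p <= 0 | p >= 1] <- NA_real_
    z
  }
  n2 <- list(m0 = 2 * d$n0, m1 = 2 * d$n1, m0p = 2 * d$n0p, m1p = 2 * d$n1p)
  out <- tibble::tibble(
    z_d = two_prop_z(ct$m1, n2$m1, ct$m0, n2$m0),
    z_r = two_prop_z(ct$m1p, n2$m1p, ct$m0p, n2$m0p),
    z_s = two_prop_z(ct$m1p, n2$m1p, ct$m0 + ct$m0p, n2$m0 + n2$m0p),
    z_c = two_prop_z(ct$m1, n2$m1, ct$m0 + ct$m0p, n2$m0 + n2$m0p),
    z_m = two_prop_z(ct$m1 + ct$m1p, n2$m1 + n2$m1p,
                     ct$m0 + ct$m0p, n2$m0 + n2$m0p)
  )
  keep <- stats::complete.cases(out)
  res <- out[keep, ]
  attr(res, "n_excluded") <- sum(!keep)
  res
}

#' Empirical null correlations of the Z-statistics
#'
#' Sample correlations between the observed Z-scores of null variants,
#' the empirical counterpart of [shared_correlations()]. Accepts either a
#' `repool_sim` object generated under a null specification or a data
#' frame of Z-score columns (e.g. from a real analysis at known-null
#' variants); with fewer than 100 rows the estimate is refused as
#' unstable.
#'
#' @param x A `repool_sim` object or a data frame of Z-score columns.
#' @return A tibble with one row per statistic pair: `stat_i`, `stat_j`,
#'   `rho_hat` and the large-sample standard error
#'   `(1 - rho_hat^2) / sqrt(n)`.
#' @export
empirical_correlations <- function(x) {
  z <- if (inherits(x, "repool_sim")) statistics_from_counts(x) else {
    tibble::as_tibble(x)
  }
  if (nrow(z) < 100) {
    stop("need at least 100 replicates for a stable correlation estimate",
         call. = FALSE)
  }
  sds <- vapply(z, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant Z column: ", paste(names(z)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  cm <- stats::cor(as.matrix(z))
  pairs <- utils::combn(colnames(cm), 2)
  tibble::tibble(
    stat_i = pairs[1, ], stat_j = pairs[2, ],
    rho_hat = cm[t(pairs)],
    se = (1 - cm[t(pairs)]^2) / sqrt(nrow(z))
  )
}

#' Empirical hit rates of the three methods
#'
#' Simulates a study, applies each method's full hit rule per replicate
#' (all three two-sided thresholds passed and all three Z-statistics of a
#' common sign) and returns the empirical rate with its binomial standard
#' error. Under a null specification the rates estimate the conserved
#' `P0`; under an effect specification they estimate power.
#'
#' @inheritParams simulate_counts
#' @param adj An [adjust_thresholds()] result.
#' @param methods Methods to score.
#' @return A tibble with columns `method`, `hits`, `n_used`, `rate`, `se`.
#' @export
empirical_rates <- function(design, adj, spec, n_rep, seed,
                            methods = c("A", "B", "C")) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(inherits(adj, "repool_thresholds"))
  sim <- simulate_counts(design, spec, n_rep, seed)
  z <- statistics_from_counts(sim)
  n_used <- nrow(z)
  rate_of <- function(method) {
    b <- method_bounds(adj, method)
    trip <- switch(method,
      A = cbind(z$z_d, z$z_r, z$z_m),
      B = cbind(z$z_d, z$z_s, z$z_m),
      C = cbind(z$z_c, z$z_s, z$z_m)
    )
    hit <- abs(trip[, 1]) > b[1] & abs(trip[, 2]) > b[2] &
      abs(trip[, 3]) > b[3] &
      (sign(trip[, 1]) == sign(trip[, 2])) &
      (sign(trip[, 2]) == sign(trip[, 3]))
    sum(hit)
  }
  hits <- vapply(methods, rate_of, numeric(1))
  rate <- hits / n_used
  tibble::tibble(
    method = methods, hits = as.integer(hits), n_used = n_used,
    rate = rate, se = sqrt(pmax(rate * (1 - rate), 1 / n_used^2) / n_used)
  )
}
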