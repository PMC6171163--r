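## Per-method rejection probabilities, power curves and summary metrics,
## and type-1 error profiles under cohort aberrance.

#' @keywords internal
method_bounds <- function(adj, method) {
  switch(method,
    A = c(z_from_p(adj$alpha), z_from_p(adj$beta), z_from_p(adj$gamma)),
    B = c(z_from_p(adj$alpha), adj$z_beta_star, z_from_p(adj$gamma)),
    C = c(z_from_p(adj$alpha), adj$z_beta_perp, z_from_p(adj$gamma))
  )
}

#' @keywords internal
method_zeta <- function(zeta, method) {
  switch(method,
    A = c(zeta$zeta_d, zeta$zeta_r, zeta$zeta_m),
    B = c(zeta$zeta_d, zeta$zeta_s, zeta$zeta_m),
    C = c(zeta$zeta_c, zeta$zeta_s, zeta$zeta_m)
  )
}

#' Probability of declaring a hit
#'
#' Rejection probability of one method for a variant with the given
#' expected Z-scores: the sum of the two shifted same-sign orthant
#' probabilities (positive- and negative-direction terms) of the method's
#' statistic triple. With all noncentralities zero this reduces to the
#' conserved null hit rate `P0`.
#'
#' @param design A one-row design data frame.
#' @param adj A [adjust_thresholds()] result (supplies `alpha`, `beta`,
#'   `gamma` and the solved `beta_star`/`beta_perp`).
#' @param zeta A one-row tibble of noncentralities, from
#'   [noncentralities()] or [zeta_for_scenario()].
#' @param method `"A"`, `"B"` or `"C"`.
#' @return A probability.
#' @export
rejection_probability <- function(design, adj, zeta,
                                  method = c("A", "B", "C")) {
  method <- match.arg(method)
  stopifnot(inherits(adj, "repool_thresholds"))
  sigma <- covariance_matrix(design, method)
  bounds <- method_bounds(adj, method)
  zv <- method_zeta(zeta, method)
  mvn_tail(sigma, bounds, shift = zv) + mvn_tail(sigma, bounds, shift = -zv)
}

## Internal: power of each requested method at one log-odds ratio.
#' @keywords internal
power_at_logor <- function(design, adj, log_or, mean_maf, methods,
                           kappa = 0) {
  spec <- freqs_from_or(design, log_or, mean_maf)
  if (kappa > 0) spec <- apply_misascertainment(spec, kappa)
  zeta <- noncentralities(design, spec)
  vapply(methods, function(m) rejection_probability(design, adj, zeta, m),
         numeric(1))
}

#' Power curve over log-odds ratios
#'
#' Rejection probability of each method along a grid of log-odds ratios,
#' for a variant with the given mean MAF (and optional misascertainment of
#' replication controls).
#'
#' @inheritParams rejection_probability
#' @param mean_maf Count-weighted mean MAF across discovery cases and
#'   controls.
#' @param log_or Numeric grid of log-odds ratios.
#' @param methods Methods to evaluate.
#' @param kappa Misascertained fraction of replication controls.
#' @return A tibble of class `repool_power_curve` with columns `log_or`,
#'   `method`, `power`. Has an [ggplot2::autoplot()] method.
#' @examples
#' \donttest{
#' des <- study_design(15000, 5000, 5000, 5000)
#' adj <- adjust_thresholds(des, 5e-6, 5e-4, 5e-8)
#' pc <- power_curve(des, adj, mean_maf = 0.1,
#'                   log_or = seq(0, 0.6, length.out = 13))
#' }
#' @export
power_curve <- function(design, adj, mean_maf, log_or,
                        methods = c("A", "B", "C"), kappa = 0) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- purrr::map(log_or, function(x) {
    p <- power_at_logor(design, adj, x, mean_maf, methods, kappa)
    tibble::tibble(log_or = x, method = methods, power = unname(p))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("repool_power_curve", class(out))
  attr(out, "mean_maf") <- mean_maf
  attr(out, "kappa") <- kappa
  out
}

## Internal: window half-width L such that every method of interest has
## power > 1 - 1e-6 at both ends.
#' @keywords internal
power_window <- function(design, adj, mean_maf, methods, kappa = 0) {
  L <- 0.5
  repeat {
    p <- c(power_at_logor(design, adj, L, mean_maf, methods, kappa),
           power_at_logor(design, adj, -L, mean_maf, methods, kappa))
    if (min(p) > 1 - 1e-6 || L > 16) break
    L <- L * 1.4
  }
  L
}

#' Average power difference between two methods
#'
#' The integral of `Power_X - Power_Y` over the log-odds ratio, evaluated
#' by adaptive quadrature on a symmetric window `[-L, L]` grown until both
#' methods' powers exceed `1 - 1e-6` at the ends (outside it the
#' difference is negligible). The raw integral is in log-OR units; the
#' windowed mean (`raw / 2L`) is also reported as a percent-style summary.
#'
#' @inheritParams power_curve
#' @param method_x,method_y Methods compared (difference is X minus Y).
#' @return A one-row tibble with `integral`, `window` (L) and
#'   `mean_difference`.
#' @export
average_power_difference <- function(design, adj, mean_maf,
                                     method_x = "B", method_y = "A",
                                     kappa = 0) {
  if (method_x == method_y) {
    return(tibble::tibble(integral = 0, window = NA_real_,
                          mean_difference = 0))
  }
  L <- power_window(design, adj, mean_maf, c(method_x, method_y), kappa)
  f <- function(x) {
    vapply(x, function(xi) {
      p <- power_at_logor(design, adj, xi, mean_maf,
                          c(method_x, method_y), kappa)
      p[1] - p[2]
    }, numeric(1))
  }
  q <- stats::integrate(f, -L, L, rel.tol = 1e-6, abs.tol = 1e-8,
                        subdivisions = 200L, stop.on.error = FALSE)
  if (!q$message %in% c("OK")) {
    stop("power-difference quadrature failed: ", q$message, call. = FALSE)
  }
  tibble::tibble(integral = q$value, window = L,
                 mean_difference = q$value / (2 * L))
}

#' Maximum power difference between two methods
#'
#' Maximizes `Power_X(x) - Power_Y(x)` over the log-odds ratio `x`:
#' a coarse grid scan followed by local golden-section refinement.
#'
#' @inheritParams average_power_difference
#' @param n_grid Number of coarse grid points.
#' @return A one-row tibble with `max_difference` and `at_log_or`.
#' @export
max_power_difference <- function(design, adj, mean_maf,
                                 method_x = "B", method_y = "A",
                                 kappa = 0, n_grid = 201) {
  if (method_x == method_y) {
    return(tibble::tibble(max_difference = 0, at_log_or = NA_real_))
  }
  L <- power_window(design, adj, mean_maf, c(method_x, method_y), kappa)
  diff_at <- function(x) {
    p <- power_at_logor(design, adj, x, mean_maf, c(method_x, method_y),
                        kappa)
    unname(p[1] - p[2])
  }
  grid <- seq(-L, L, length.out = n_grid)
  vals <- vapply(grid, diff_at, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  opt <- stats::optimize(diff_at, c(lo, hi), maximum = TRUE, tol = 1e-7)
  if (opt$objective < vals[i]) {
    opt <- list(maximum = grid[i], objective = vals[i])
  }
  tibble::tibble(max_difference = opt$objective, at_log_or = opt$maximum)
}

#' Additional independent controls needed to match shared-control power
#'
#' Smallest number of extra replication controls that method A (with
#' otherwise unchanged thresholds) would need for its power at the stated
#' effect to reach method B's power on the unmodified design. Method A's
#' power is recomputed for each candidate count (correlation structure and
#' noncentralities both depend on it); the search is monotone bisection.
#'
#' @inheritParams average_power_difference
#' @param log_or Log-odds ratio at which powers are matched.
#' @param cap Upper search limit; if parity is unreachable below `cap` the
#'   cap is reported with `reached_parity = FALSE`.
#' @return A one-row tibble with `additional_controls`, `power_B`
#'   (target), `power_A_at` (method-A power at the returned count) and
#'   `reached_parity`.
#' @export
controls_for_parity <- function(design, adj, mean_maf, log_or,
                                kappa = 0, cap = 200000L) {
  d <- as_design(design)
  spec <- freqs_from_or(design, log_or, mean_maf)
  if (kappa > 0) spec <- apply_misascertainment(spec, kappa)
  target <- rejection_probability(design, adj,
                                  noncentralities(design, spec), "B")
  power_a <- function(extra) {
    des2 <- study_design(d$n0, d$n1, d$n0p + extra, d$n1p)
    spec2 <- freqs_from_or(des2, log_or, mean_maf)
    if (kappa > 0) spec2 <- apply_misascertainment(spec2, kappa)
    rejection_probability(des2, adj, noncentralities(des2, spec2), "A")
  }
  if (power_a(0) >= target) {
    return(tibble::tibble(additional_controls = 0L, power_B = target,
                          power_A_at = power_a(0), reached_parity = TRUE))
  }
  cap <- as.integer(cap)
  lo <- 0L
  hi <- min(256L, cap)
  while (power_a(hi) < target && hi < cap) {
    lo <- hi
    hi <- min(hi * 4L, cap)
  }
  if (power_a(hi) < target) {
    return(tibble::tibble(additional_controls = as.integer(cap),
                          power_B = target, power_A_at = power_a(hi),
                          reached_parity = FALSE))
  }
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (power_a(mid) >= target) hi <- mid else lo <- mid
  }
  tibble::tibble(additional_controls = hi, power_B = target,
                 power_A_at = power_a(hi), reached_parity = TRUE)
}

#' Type-1 error profile under cohort aberrance
#'
#' False-positive rate of each method along a grid of noncentralities for
#' an aberrance scenario (a set of cohorts whose expected MAF deviates
#' systematically from the population value). At zero aberrance all rates
#' equal the conserved `P0`; as the driving noncentrality grows, each rate
#' approaches its analytic limit (e.g. for aberrance confined to the
#' discovery cases, `beta/2`, `beta_star/2` and `beta_perp/2` for methods
#' A, B, C).
#'
#' @inheritParams rejection_probability
#' @param cohorts Aberrant cohort set (see [zeta_for_scenario()]).
#' @param zeta_grid Values of the driving noncentrality.
#' @param weights Relative offset per cohort (sign encodes direction).
#' @param driving Driving statistic name; defaulted by scenario.
#' @param methods Methods to profile.
#' @return A tibble of class `repool_error_profile` with columns
#'   `scenario`, `zeta`, `method`, `rate`.
#' @export
type1_profile <- function(design, adj, cohorts, zeta_grid, weights = 1,
                          driving = NULL, methods = c("A", "B", "C")) {
  methods <- match.arg(methods, several.ok = TRUE)
  label <- paste(cohorts, collapse = "+")
  rows <- purrr::map(zeta_grid, function(z) {
    zv <- zeta_for_scenario(design, cohorts, z, weights, driving)
    rates <- vapply(methods, function(m) {
      rejection_probability(design, adj, zv, m)
    }, numeric(1))
    tibble::tibble(scenario = label, zeta = z, method = methods,
                   rate = unname(rates))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("repool_error_profile", class(out))
  out
}

#' Analytic bound on the shared-vs-standard error-rate difference
#'
#' Approximate upper bound, in the `gamma = 1` regime, on the difference
#' between method B's and method A's false-positive rates under aberrance
#' in the replication cases (`which = "C1p"`, bound on `R_B - R_A`) or the
#' replication controls (`which = "C0p"`, bound on `R_A - R_B`):
#' `alpha / (2 sqrt(2 pi)) * (k / sqrt(1 - rho_ds^2) - 1) * z_beta`, with
#' `k = zeta_s / zeta_r` the shared-to-independent noncentrality ratio of
#' the scenario. The bound is far below `alpha / 2` for typical GWAS
#' thresholds.
#'
#' @inheritParams null_hit_rate
#' @param beta Unadjusted replication threshold.
#' @param which Aberrant replication cohort.
#' @return A one-row tibble with `k`, `rho_ds` and `bound`.
#' @export
rb_ra_bound <- function(design, alpha, beta, which = c("C1p", "C0p")) {
  which <- match.arg(which)
  d <- as_design(design)
  k <- if (which == "C1p") {
    sqrt((d$n0 + d$n0p) * (d$n0p + d$n1p) /
           (d$n0p * (d$n0 + d$n0p + d$n1p)))
  } else {
    sqrt(d$n0p * (d$n0p + d$n1p) /
           ((d$n0 + d$n0p) * (d$n0 + d$n0p + d$n1p)))
  }
  rho <- shared_correlations(design)$rho_ds
  bound <- alpha / (2 * sqrt(2 * pi)) *
    (k / sqrt(1 - rho^2) - 1) * z_from_p(beta)
  tibble::tibble(k = k, rho_ds = rho, bound = bound)
}
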