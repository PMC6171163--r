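## Effect specification: translate odds-ratio / allele-frequency settings
## (including aberrance and control misascertainment) into the expected
## Z-scores (noncentralities) of the five statistics.

#' Build a cohort frequency specification
#'
#' @param mu0,mu1 Population minor-allele frequencies of discovery controls
#'   and cases, strictly inside (0, 1).
#' @param mu0p,mu1p Replication-cohort frequencies; default to `mu0`, `mu1`
#'   (a "true association" is the same in both stages).
#' @return A one-row tibble of class `repool_freqs` with columns `mu0`,
#'   `mu1`, `mu0p`, `mu1p`.
#' @export
frequency_spec <- function(mu0, mu1, mu0p = mu0, mu1p = mu1) {
  f <- tibble::tibble(mu0 = mu0, mu1 = mu1, mu0p = mu0p, mu1p = mu1p)
  validate_freqs(f)
  class(f) <- c("repool_freqs", class(f))
  f
}

#' @keywords internal
validate_freqs <- function(spec) {
  req <- c("mu0", "mu1", "mu0p", "mu1p")
  missing <- setdiff(req, names(spec))
  if (length(missing) > 0) {
    stop("frequency spec is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in req) {
    x <- spec[[col]]
    if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
      stop("frequency '", col, "' must lie strictly inside (0, 1)",
           call. = FALSE)
    }
  }
  invisible(spec)
}

#' Cohort frequencies from a log-odds-ratio and mean MAF
#'
#' Solves for control/case frequencies `(mu0, mu1)` such that
#' `log(mu1 (1 - mu0) / (mu0 (1 - mu1))) = log_or` and the count-weighted
#' mean frequency across discovery cases and controls
#' `(n0 mu0 + n1 mu1) / (n0 + n1)` equals `mean_maf`. The replication
#' frequencies are set equal (`mu0p = mu0`, `mu1p = mu1`), i.e. a true
#' association identical in both stages. Solved to a constraint residual
#' below `1e-12`.
#'
#' @param design A one-row design data frame (supplies the case/control
#'   weighting of the mean).
#' @param log_or Log odds ratio of the minor allele, cases vs controls.
#' @param mean_maf Count-weighted mean minor-allele frequency in (0, 1).
#' @return A `repool_freqs` tibble.
#' @examples
#' freqs_from_or(study_design(15000, 5000, 5000, 5000),
#'               log_or = log(1.3), mean_maf = 0.1)
#' @export
freqs_from_or <- function(design, log_or, mean_maf) {
  d <- as_design(design)
  if (!is.finite(mean_maf) || mean_maf <= 0 || mean_maf >= 1) {
    stop("mean_maf must lie in (0, 1)", call. = FALSE)
  }
  if (log_or == 0) {
    return(frequency_spec(mean_maf, mean_maf))
  }
  mu1_of <- function(mu0) {
    odds <- exp(log_or) * mu0 / (1 - mu0)
    odds / (1 + odds)
  }
  w0 <- d$n0 / (d$n0 + d$n1)
  w1 <- d$n1 / (d$n0 + d$n1)
  g <- function(mu0) w0 * mu0 + w1 * mu1_of(mu0) - mean_maf
  eps <- 1e-12
  lo <- eps
  hi <- 1 - eps
  if (g(lo) > 0 || g(hi) < 0) {
    stop("mean_maf is unattainable for this log-odds ratio", call. = FALSE)
  }
  mu0 <- stats::uniroot(g, c(lo, hi), tol = 1e-15)$root
  # one Newton polish for |constraint| < 1e-12
  for (i in 1:3) {
    grad <- (g(mu0 + 1e-8) - g(mu0 - 1e-8)) / 2e-8
    mu0 <- mu0 - g(mu0) / grad
  }
  mu0 <- min(max(mu0, eps), 1 - eps)
  frequency_spec(mu0, mu1_of(mu0))
}

#' Misascertainment of replication controls
#'
#' If a proportion `kappa` of nominal replication controls are actually
#' drawn from the case population, the expected replication-control
#' frequency becomes `mu0p = (1 - kappa) * mu0 + kappa * mu1`. All other
#' fields are unchanged.
#'
#' @param spec A `repool_freqs` specification.
#' @param kappa Misascertained fraction in `[0, 1]`.
#' @return The modified `repool_freqs` tibble.
#' @export
apply_misascertainment <- function(spec, kappa) {
  validate_freqs(spec)
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) ||
      kappa < 0 || kappa > 1) {
    stop("kappa must lie in [0, 1]", call. = FALSE)
  }
  spec$mu0p <- (1 - kappa) * spec$mu0 + kappa * spec$mu1
  spec
}

#' Offset cohort frequencies (aberrance)
#'
#' Adds a systematic frequency offset to named cohorts, modelling
#' confounding or measurement error that shifts a cohort's expected MAF
#' away from its population value. Applied to a null base specification
#' this realizes the single-cohort aberrance scenarios: e.g. aberrance in
#' `C1` only gives nonzero expected `z_d`, `z_c`, `z_m` with
#' `z_r`, `z_s` unaffected.
#'
#' @param spec A base `repool_freqs` specification (typically null: all
#'   four frequencies equal).
#' @param cohorts Character vector among `"C0"`, `"C1"`, `"C0p"`, `"C1p"`.
#' @param offsets Frequency offsets, recycled along `cohorts`.
#' @return The offset `repool_freqs` tibble (validated to stay inside
#'   (0, 1)).
#' @export
aberrance_pattern <- function(spec, cohorts, offsets) {
  validate_freqs(spec)
  if (length(cohorts) == 0) return(spec)
  cohorts <- match.arg(cohorts, c("C0", "C1", "C0p", "C1p"),
                       several.ok = TRUE)
  offsets <- rep_len(offsets, length(cohorts))
  field <- c(C0 = "mu0", C1 = "mu1", C0p = "mu0p", C1p = "mu1p")
  for (i in seq_along(cohorts)) {
    spec[[field[[cohorts[i]]]]] <- spec[[field[[cohorts[i]]]]] + offsets[i]
  }
  validate_freqs(spec)
  spec
}

#' Expected Z-scores (noncentralities) of the five statistics
#'
#' Evaluates the expected value of each signed Z-statistic under a cohort
#' frequency specification, using the first-order normal approximation:
#' each expectation is `sqrt(2 n_eff)` times the relevant frequency
#' contrast over `sqrt(mu_bar (1 - mu_bar))`, where `n_eff` is the
#' harmonic-style effective sample size of the two compared groups and
#' `mu_bar` is a single count-weighted mean frequency over all four
#' cohorts (one consistent value keeps noncentrality ratios exact).
#'
#' @param design A one-row design data frame.
#' @param spec A `repool_freqs` specification.
#' @return A one-row tibble with columns `zeta_d`, `zeta_r`, `zeta_s`,
#'   `zeta_c`, `zeta_m`.
#' @examples
#' noncentralities(study_design(15000, 5000, 5000, 5000),
#'                 freqs_from_or(study_design(15000, 5000, 5000, 5000),
#'                               log(1.3), 0.1))
#' @export
noncentralities <- function(design, spec) {
  d <- as_design(design)
  validate_freqs(spec)
  mu <- c(spec$mu0, spec$mu1, spec$mu0p, spec$mu1p)
  n <- c(d$n0, d$n1, d$n0p, d$n1p)
  mu_bar <- sum(n * mu) / sum(n)
  denom <- sqrt(mu_bar * (1 - mu_bar))
  eff <- function(na, nb) sqrt(2 * na * nb / (na + nb))
  pool0 <- (d$n0 * spec$mu0 + d$n0p * spec$mu0p) / (d$n0 + d$n0p)
  pool1 <- (d$n1 * spec$mu1 + d$n1p * spec$mu1p) / (d$n1 + d$n1p)
  tibble::tibble(
    zeta_d = eff(d$n0, d$n1) * (spec$mu1 - spec$mu0) / denom,
    zeta_r = eff(d$n0p, d$n1p) * (spec$mu1p - spec$mu0p) / denom,
    zeta_s = eff(d$n0 + d$n0p, d$n1p) * (spec$mu1p - pool0) / denom,
    zeta_c = eff(d$n0 + d$n0p, d$n1) * (spec$mu1 - pool0) / denom,
    zeta_m = eff(d$n0 + d$n0p, d$n1 + d$n1p) * (pool1 - pool0) / denom
  )
}

#' Noncentrality vector for an aberrance scenario, on the zeta scale
#'
#' Computes the expected-Z pattern generated by unit frequency offsets in
#' the named cohorts and rescales it so that the driving statistic equals
#' `zeta`. Because every expected Z shares the same `1/sqrt(mu_bar (1 -
#' mu_bar))` factor, the ratios between components are frequency-free and
#' this parameterization is exact, which makes it suitable for limit
#' studies (`zeta` arbitrarily large).
#'
#' @param design A one-row design data frame.
#' @param cohorts Aberrant cohorts (subset of `"C0"`, `"C1"`, `"C0p"`,
#'   `"C1p"`); an empty set returns the all-zero vector.
#' @param zeta Value imposed on the driving statistic.
#' @param weights Relative offset direction/size per cohort (recycled);
#'   use opposite signs for opposite-direction combined aberrance.
#' @param driving Which statistic `zeta` refers to; defaults to `zeta_d`
#'   for scenarios touching the discovery cohorts and `zeta_r` otherwise.
#' @return A one-row tibble of the five noncentralities.
#' @export
zeta_for_scenario <- function(design, cohorts, zeta, weights = 1,
                              driving = NULL) {
  if (length(cohorts) == 0 || zeta == 0) {
    return(tibble::tibble(zeta_d = 0, zeta_r = 0, zeta_s = 0,
                          zeta_c = 0, zeta_m = 0))
  }
  cohorts <- match.arg(cohorts, c("C0", "C1", "C0p", "C1p"),
                       several.ok = TRUE)
  if (is.null(driving)) {
    driving <- if (any(cohorts %in% c("C0", "C1"))) "zeta_d" else "zeta_r"
  }
  # linearize: unit pattern with a tiny offset around a fixed base, then
  # scale; ratios are exact because Eq-ratios are offset-linear at fixed
  # mu_bar
  base <- 0.5
  delta <- 1e-4
  spec <- frequency_spec(base, base)
  spec <- aberrance_pattern(spec, cohorts,
                            delta * rep_len(weights, length(cohorts)))
  # hold mu_bar at the base value for exact linearity
  d <- as_design(design)
  z <- noncentralities_fixed_mubar(d, spec, base)
  pivot <- z[[driving]]
  if (abs(pivot) < .Machine$double.eps) {
    stop("driving statistic '", driving,
         "' is unaffected by aberrance in ", paste(cohorts, collapse = ","),
         call. = FALSE)
  }
  dplyr::mutate(z, dplyr::across(dplyr::everything(), ~ .x * zeta / pivot))
}

#' @keywords internal
noncentralities_fixed_mubar <- function(d, spec, mu_bar) {
  denom <- sqrt(mu_bar * (1 - mu_bar))
  eff <- function(na, nb) sqrt(2 * na * nb / (na + nb))
  pool0 <- (d$n0 * spec$mu0 + d$n0p * spec$mu0p) / (d$n0 + d$n0p)
  pool1 <- (d$n1 * spec$mu1 + d$n1p * spec$mu1p) / (d$n1 + d$n1p)
  tibble::tibble(
    zeta_d = eff(d$n0, d$n1) * (spec$mu1 - spec$mu0) / denom,
    zeta_r = eff(d$n0p, d$n1p) * (spec$mu1p - spec$mu0p) / denom,
    zeta_s = eff(d$n0 + d$n0p, d$n1p) * (spec$mu1p - pool0) / denom,
    zeta_c = eff(d$n0 + d$n0p, d$n1) * (spec$mu1 - pool0) / denom,
    zeta_m = eff(d$n0 + d$n0p, d$n1 + d$n1p) * (pool1 - pool0) / denom
  )
}
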