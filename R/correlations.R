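## Null correlation structure of the five association Z-statistics.
##
## Each statistic compares allele-frequency estimates between two pooled
## cohort groups:
##   d : C1  vs C0           (discovery)
##   r : C1' vs C0'          (replication, independent controls)
##   s : C1' vs C0 u C0'     (replication, shared controls)
##   c : C1  vs C0 u C0'     (discovery, fully pooled controls)
##   m : C1 u C1' vs C0 u C0'  (meta-analytic)
## Writing each Z as a linear combination of the four per-cohort frequency
## estimators m_i (independent, var(m_i) = mu(1-mu)/(2 n_i) under the null,
## pooled frequencies as count-weighted means), the null correlation of two
## Z's is the shared-cohort covariance over the product of standard errors.
## The common factor mu(1-mu) cancels, so correlations depend on the four
## counts only.

## Coefficient vectors of the five statistics over (m0, m1, m0p, m1p),
## rows d, r, s, c, m (numerators, before division by the standard error).
#' @keywords internal
stat_coefs <- function(d) {
  w0  <- d$n0  / (d$n0 + d$n0p)   # weight of C0  in the pooled control mean
  w0p <- d$n0p / (d$n0 + d$n0p)
  v1  <- d$n1  / (d$n1 + d$n1p)   # weight of C1  in the pooled case mean
  v1p <- d$n1p / (d$n1 + d$n1p)
  m <- rbind(
    d = c(-1,   1,    0,   0),
    r = c( 0,   0,   -1,   1),
    s = c(-w0,  0,  -w0p,  1),
    c = c(-w0,  1,  -w0p,  0),
    m = c(-w0,  v1, -w0p, v1p)
  )
  colnames(m) <- c("m0", "m1", "m0p", "m1p")
  m
}

## Null variance weights of the four frequency estimators, up to mu(1-mu).
#' @keywords internal
cohort_var_weights <- function(d) {
  c(m0 = 1 / (2 * d$n0), m1 = 1 / (2 * d$n1),
    m0p = 1 / (2 * d$n0p), m1p = 1 / (2 * d$n1p))
}

## Full 5x5 null correlation matrix of (z_d, z_r, z_s, z_c, z_m).
#' @keywords internal
corr_matrix5 <- function(d) {
  cf <- stat_coefs(d)
  a <- cohort_var_weights(d)
  cov <- cf %*% (a * t(cf))
  stats::cov2cor(cov)
}

#' Null correlations induced by sample sharing
#'
#' Computes, for each design row, the seven pairwise null correlations of
#' the five association Z-statistics (discovery `z_d`, replication `z_r`,
#' shared-control replication `z_s`, pooled-control discovery `z_c`,
#' meta-analytic `z_m`) that arise from cohort sharing. `rho_dr` is exactly
#' zero (disjoint cohorts); all others are deterministic functions of the
#' four counts and invariant under common scaling of the counts.
#'
#' @param design A data frame of designs with columns `n0`, `n1`, `n0p`,
#'   `n1p` (one or more rows), e.g. from [study_design()].
#' @return The input with columns `rho_dr`, `rho_ds`, `rho_dm`, `rho_rm`,
#'   `rho_sm`, `rho_cs`, `rho_cm` added, as a tibble.
#' @examples
#' shared_correlations(study_design(5000, 5000, 5000, 5000))
#' @export
shared_correlations <- function(design) {
  validate_design(design)
  rows <- purrr::map(seq_len(nrow(design)), function(i) {
    d <- as_design(design[i, ])
    r5 <- corr_matrix5(d)
    tibble::tibble(
      rho_dr = 0,
      rho_ds = r5["d", "s"], rho_dm = r5["d", "m"],
      rho_rm = r5["r", "m"], rho_sm = r5["s", "m"],
      rho_cs = r5["c", "s"], rho_cm = r5["c", "m"]
    )
  })
  dplyr::bind_cols(tibble::as_tibble(design), dplyr::bind_rows(rows))
}

#' Per-method covariance matrix of the three tested Z-statistics
#'
#' Assembles the 3x3 null correlation matrix of the statistic triple tested
#' by each design: method A tests `(z_d, z_r, z_m)`, method B
#' `(z_d, z_s, z_m)` and method C `(z_c, z_s, z_m)`. `sigma_A` is singular
#' exactly when the control/case ratio matches between stages
#' (`n0/n1 = n0p/n1p`); `sigma_C` is singular for every design because the
#' meta statistic is a fixed linear combination of the other two.
#'
#' @param design A one-row design data frame.
#' @param method `"A"`, `"B"` or `"C"`.
#' @return A 3x3 symmetric correlation matrix with dimnames naming the
#'   statistics.
#' @examples
#' covariance_matrix(study_design(5000, 5000, 5000, 5000), "B")
#' @export
covariance_matrix <- function(design, method = c("A", "B", "C")) {
  method <- match.arg(method)
  d <- as_design(design)
  triple <- switch(method,
    A = c("d", "r", "m"),
    B = c("d", "s", "m"),
    C = c("c", "s", "m")
  )
  r5 <- corr_matrix5(d)
  r5[triple, triple]
}

#' Detect and resolve a linearly dependent third statistic
#'
#' Tests whether a 3x3 correlation matrix is (near-)singular and, if so,
#' returns the coefficients `(a, b)` such that the third statistic equals
#' `a * z1 + b * z2` exactly under the null. Reduction is triggered when
#' the smallest eigenvalue is below `tol` times the largest (default
#' `1e-8`, which also covers near-singular matrices with condition number
#' above `1e8`); the downstream orthant integrals then integrate over the
#' two free coordinates with the third constraint as a half-plane.
#'
#' @param sigma A 3x3 symmetric correlation matrix (unit diagonal).
#' @param tol Relative eigenvalue threshold for singularity.
#' @return A list with `full_rank` (logical) and, when rank-deficient,
#'   coefficients `a` and `b`.
#' @examples
#' reduce_singular(covariance_matrix(study_design(5000, 5000, 5000, 5000), "C"))
#' @export
reduce_singular <- function(sigma, tol = 1e-8) {
  stopifnot(is.matrix(sigma), all(dim(sigma) == c(3, 3)))
  if (max(abs(sigma - t(sigma))) > 1e-12 || max(abs(diag(sigma) - 1)) > 1e-12) {
    stop("sigma must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) {
    stop("sigma is not a valid correlation matrix (negative eigenvalue)",
         call. = FALSE)
  }
  if (min(ev) >= tol * max(ev)) {
    return(list(full_rank = TRUE))
  }
  r12 <- sigma[1, 2]
  if (abs(1 - r12^2) < 1e-12) {
    stop("first two statistics are themselves collinear; cannot reduce",
         call. = FALSE)
  }
  # Regression of z3 on (z1, z2); with zero residual variance this is the
  # exact linear dependence. Closed form matches the pooled-design formula
  # a = (r13 - r12 r23) / (1 - r12^2), b = (r23 - r12 r13) / (1 - r12^2).
  a <- (sigma[1, 3] - r12 * sigma[2, 3]) / (1 - r12^2)
  b <- (sigma[2, 3] - r12 * sigma[1, 3]) / (1 - r12^2)
  list(full_rank = FALSE, a = a, b = b)
}
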