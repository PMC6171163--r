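## Threshold calibration: the baseline joint null hit rate P0 of the
## standard design (method A) and the adjusted replication thresholds
## beta* (method B) and beta-perp (method C) that conserve it.

## Two-sided p-value threshold -> positive z threshold and back
#' @keywords internal
z_from_p <- function(p) stats::qnorm(p / 2, lower.tail = FALSE)
#' @keywords internal
p_from_z <- function(z) 2 * stats::pnorm(z, lower.tail = FALSE)

#' @keywords internal
validate_thresholds <- function(alpha, beta, gamma) {
  for (x in list(alpha = alpha, beta = beta, gamma = gamma)) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0 || x > 1) {
      stop("alpha, beta, gamma must lie in (0, 1]", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Joint null hit rate of a two-stage design
#'
#' Probability, under the global null (all four cohort frequencies equal),
#' that a variant passes all three of the method's thresholds with a
#' consistent effect direction. The hit rule "all effects in the same
#' direction" makes this twice the positive-orthant probability of the
#' method's statistic triple.
#'
#' @param design A one-row design data frame.
#' @param alpha,gamma Two-sided p-value thresholds for the discovery and
#'   meta-analytic statistics, in `(0, 1]`.
#' @param beta_repl The method's replication-stage two-sided threshold
#'   (`beta` for method A, a solved `beta_star`/`beta_perp` for B/C).
#' @param method `"A"`, `"B"` or `"C"`.
#' @return A probability.
#' @examples
#' null_hit_rate(study_design(15000, 5000, 5000, 5000),
#'               alpha = 5e-6, beta_repl = 5e-4, gamma = 5e-8, method = "A")
#' @export
null_hit_rate <- function(design, alpha, beta_repl, gamma,
                          method = c("A", "B", "C")) {
  method <- match.arg(method)
  validate_thresholds(alpha, beta_repl, gamma)
  sigma <- covariance_matrix(design, method)
  bounds <- c(z_from_p(alpha), z_from_p(beta_repl), z_from_p(gamma))
  2 * mvn_tail(sigma, bounds)
}

#' Asymptotic (large z_alpha) replication threshold on the z scale
#'
#' First-order approximation `sqrt(1 - rho^2) * z_beta + rho * z_alpha` to
#' the solved adjusted threshold, with `rho = rho_ds` for method B or
#' `rho_cs` for method C. The exact solution approaches this from above as
#' `z_alpha` grows, so it serves as solver initialization and as a lower
#' bracket anchor.
#'
#' @inheritParams null_hit_rate
#' @param beta The unadjusted replication threshold.
#' @param method `"B"` or `"C"`.
#' @return The approximate threshold on the z scale.
#' @export
asymptotic_beta_star <- function(design, alpha, beta, method = c("B", "C")) {
  method <- match.arg(method)
  rho <- shared_correlations(design)[[if (method == "B") "rho_ds" else "rho_cs"]]
  sqrt(1 - rho^2) * z_from_p(beta) + rho * z_from_p(alpha)
}

## Solve the method's replication z-threshold so its null hit rate equals
## `target`. Root-finding on the log hit rate over z in
## [max(z_beta, asymptote), z_beta + rho z_alpha + 6].
#' @keywords internal
solve_repl_threshold <- function(design, alpha, beta, gamma, method, target,
                                 rate_fun = NULL) {
  if (is.null(rate_fun)) {
    rate_fun <- function(z) {
      null_hit_rate(design, alpha, p_from_z(z), gamma, method)
    }
  }
  rho <- shared_correlations(design)[[if (method == "B") "rho_ds" else "rho_cs"]]
  z_b <- z_from_p(beta)
  # The adjusted threshold always exceeds z_beta (beta* < beta). The
  # large-z_alpha asymptote is a lower bound only when gamma is not more
  # stringent than beta; with gamma << beta the solution can fall below
  # it, so the bracket anchors at z_beta and the asymptote only caps the
  # upper end.
  lower <- z_b
  upper <- max(z_b, asymptotic_beta_star(design, alpha, beta, method)) +
    abs(rho) * z_from_p(alpha) + 6
  g <- function(z) log(rate_fun(z)) - log(target)
  g_lo <- g(lower)
  if (g_lo < 0) {
    # solution can sit marginally below the anchor through numerical
    # round-off when rho ~ 0; widen slightly, then fail loudly
    lower <- lower - 1e-6
    g_lo <- g(lower)
    if (g_lo < 0) {
      if (g_lo > -1e-8) return(lower)
      stop("no root in bracket: thresholds are degenerate", call. = FALSE)
    }
  }
  g_hi <- g(upper)
  tries <- 0
  while (g_hi > 0 && tries < 5) {
    upper <- upper + 4
    g_hi <- g(upper)
    tries <- tries + 1
  }
  if (g_hi > 0) stop("no root in bracket: thresholds are degenerate",
                     call. = FALSE)
  stats::uniroot(g, c(lower, upper),
    f.lower = g_lo, f.upper = g_hi, tol = 1e-13
  )$root
}

#' Solve the adjusted replication thresholds beta* and beta-perp
#'
#' Calibrates the replication-stage thresholds of the shared-control design
#' (method B) and the fully-pooled-control design (method C) so each
#' conserves the joint null hit rate `P0` of the standard design (method A)
#' run at `(alpha, beta, gamma)`. Always `beta_perp < beta_star < beta`.
#'
#' With `gamma = 1` the default (`convention = "directional"`) retains the
#' sign-agreement requirement on the meta statistic (its z-threshold is 0);
#' `convention = "nondirectional"` instead matches the two-threshold joint
#' rate without any direction constraint, so that for independent
#' statistics the conserved rate is exactly `alpha * beta`.
#'
#' @inheritParams null_hit_rate
#' @param beta The unadjusted replication threshold of method A, in (0, 1).
#' @param convention Hit-rule convention used when `gamma = 1`; ignored
#'   otherwise.
#' @return An object of class `repool_thresholds`: a list carrying the
#'   design, the input thresholds, `p0`, `beta_star`, `beta_perp`, the
#'   solver residuals (absolute, probability scale) and the null
#'   correlations used. Has [tidy()] and [glance()] methods.
#' @examples
#' adj <- adjust_thresholds(study_design(15000, 5000, 5000, 5000),
#'                          alpha = 5e-6, beta = 5e-4, gamma = 5e-8)
#' tidy(adj)
#' @export
adjust_thresholds <- function(design, alpha, beta, gamma,
                              convention = c("directional", "nondirectional")) {
  convention <- match.arg(convention)
  validate_thresholds(alpha, beta, gamma)
  if (beta >= 1) stop("beta must lie in (0, 1) to be adjustable",
                      call. = FALSE)
  design <- tibble::as_tibble(as_design(design))
  rho <- shared_correlations(design)
  if (gamma == 1 && convention == "nondirectional") {
    target <- alpha * beta
    rate_b <- function(z) {
      joint_twosided_rate(z_from_p(alpha), z, rho$rho_ds)
    }
    rate_c <- function(z) {
      joint_twosided_rate(z_from_p(alpha), z, rho$rho_cs)
    }
    zs <- solve_repl_threshold(design, alpha, beta, gamma, "B", target, rate_b)
    zp <- solve_repl_threshold(design, alpha, beta, gamma, "C", target, rate_c)
    res_b <- abs(rate_b(zs) - target)
    res_c <- abs(rate_c(zp) - target)
  } else {
    target <- null_hit_rate(design, alpha, beta, gamma, "A")
    zs <- solve_repl_threshold(design, alpha, beta, gamma, "B", target)
    zp <- solve_repl_threshold(design, alpha, beta, gamma, "C", target)
    res_b <- abs(null_hit_rate(design, alpha, p_from_z(zs), gamma, "B") - target)
    res_c <- abs(null_hit_rate(design, alpha, p_from_z(zp), gamma, "C") - target)
  }
  structure(
    list(
      design = design,
      alpha = alpha, beta = beta, gamma = gamma,
      convention = convention,
      p0 = target,
      beta_star = p_from_z(zs), beta_perp = p_from_z(zp),
      z_beta_star = zs, z_beta_perp = zp,
      residual = c(beta_star = res_b, beta_perp = res_c),
      correlations = rho
    ),
    class = "repool_thresholds"
  )
}

## Two-sided joint rate Pr(|z1| > a, |z2| > b) for correlation rho,
## without any sign-agreement requirement.
#' @keywords internal
joint_twosided_rate <- function(a, b, rho) {
  2 * (bvn_tail(a, b, rho) + bvn_tail(a, b, -rho))
}

#' @export
print.repool_thresholds <- function(x, ...) {
  d <- x$design
  cat("Two-stage threshold adjustment\n")
  cat(sprintf("  design: n0=%d n1=%d n0'=%d n1'=%d\n",
              d$n0, d$n1, d$n0p, d$n1p))
  cat(sprintf("  alpha=%g beta=%g gamma=%g (%s)\n",
              x$alpha, x$beta, x$gamma, x$convention))
  cat(sprintf("  P0         = %.6e\n", x$p0))
  cat(sprintf("  beta*  (B) = %.6e   (z = %.6f)\n", x$beta_star, x$z_beta_star))
  cat(sprintf("  beta-p (C) = %.6e   (z = %.6f)\n", x$beta_perp, x$z_beta_perp))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an adjusted-thresholds object
#'
#' @param x A `repool_thresholds` object.
#' @param ... Unused.
#' @return One row per solved quantity (`p0`, `beta_star`, `beta_perp`)
#'   with its value, z-scale value and solver residual.
#' @export
tidy.repool_thresholds <- function(x, ...) {
  tibble::tibble(
    term = c("p0", "beta_star", "beta_perp"),
    estimate = c(x$p0, x$beta_star, x$beta_perp),
    z_value = c(NA_real_, x$z_beta_star, x$z_beta_perp),
    residual = c(NA_real_, x$residual[["beta_star"]], x$residual[["beta_perp"]])
  )
}

#' One-row summary of an adjusted-thresholds object
#'
#' @param x A `repool_thresholds` object.
#' @param ... Unused.
#' @return A one-row tibble with the design, thresholds, solved values and
#'   the sharing-induced correlations they depend on.
#' @export
glance.repool_thresholds <- function(x, ...) {
  dplyr::bind_cols(
    x$design,
    tibble::tibble(
      alpha = x$alpha, beta = x$beta, gamma = x$gamma,
      convention = x$convention,
      p0 = x$p0, beta_star = x$beta_star, beta_perp = x$beta_perp,
      rho_ds = x$correlations$rho_ds, rho_cs = x$correlations$rho_cs
    )
  )
}
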