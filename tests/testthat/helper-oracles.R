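# Independent oracles used across the suite.
#
# mc_corr_oracle: empirical correlations of the five Z-statistics from raw
#   binomial sampling (no package statistics code).
# mc_hit_rate_cond: Monte-Carlo null hit rate of a statistic triple by
#   conditioning on the first coordinate (truncated-normal draw) and
#   Rao-Blackwellizing the third via the standard conditional-normal CDF.
#   Uses only base R; shares no code path with the package's quadrature.

# Draw Z-statistic tuples from raw binomial cohort counts (null or not).
mc_z_draws <- function(n, mu, n_rep, seed) {
  set.seed(seed)
  n2 <- 2 * n
  cnt <- cbind(
    rbinom(n_rep, n2[1], mu[1]), rbinom(n_rep, n2[2], mu[2]),
    rbinom(n_rep, n2[3], mu[3]), rbinom(n_rep, n2[4], mu[4])
  )
  zf <- function(ca, na2, cb, nb2) {
    fa <- ca / na2
    fb <- cb / nb2
    p <- (ca + cb) / (na2 + nb2)
    (fa - fb) / sqrt(p * (1 - p) * (1 / na2 + 1 / nb2))
  }
  data.frame(
    z_d = zf(cnt[, 2], n2[2], cnt[, 1], n2[1]),
    z_r = zf(cnt[, 4], n2[4], cnt[, 3], n2[3]),
    z_s = zf(cnt[, 4], n2[4], cnt[, 1] + cnt[, 3], n2[1] + n2[3]),
    z_c = zf(cnt[, 2], n2[2], cnt[, 1] + cnt[, 3], n2[1] + n2[3]),
    z_m = zf(cnt[, 2] + cnt[, 4], n2[2] + n2[4],
             cnt[, 1] + cnt[, 3], n2[1] + n2[3])
  )
}

mc_corr_oracle <- function(n, mu, n_rep, seed) {
  z <- mc_z_draws(n, rep(mu, 4), n_rep, seed)
  z <- z[stats::complete.cases(z), ]
  list(cor = stats::cor(as.matrix(z)), n = nrow(z))
}

# Null hit rate 2 * Pr(Z1 > b1, Z2 > b2, Z3 > b3) for Z ~ N(0, sigma),
# full-rank sigma. Returns estimate and MC standard error.
mc_hit_rate_cond <- function(sigma, bounds, n_draw, seed) {
  set.seed(seed)
  p1 <- pnorm(bounds[1], lower.tail = FALSE)
  # z1 | z1 > b1 by inverse-CDF
  u <- runif(n_draw)
  z1 <- qnorm(p1 * u, lower.tail = FALSE)
  # z2 | z1
  r12 <- sigma[1, 2]
  r13 <- sigma[1, 3]
  r23 <- sigma[2, 3]
  s2 <- sqrt(1 - r12^2)
  z2 <- r12 * z1 + s2 * rnorm(n_draw)
  # z3 | z1, z2 (regression coefficients from the 2x2 system)
  det12 <- 1 - r12^2
  a1 <- (r13 - r12 * r23) / det12
  a2 <- (r23 - r12 * r13) / det12
  v3 <- 1 - (a1 * r13 + a2 * r23)
  mu3 <- a1 * z1 + a2 * z2
  g <- ifelse(z2 > bounds[2],
    if (v3 > 1e-12) {
      pnorm((bounds[3] - mu3) / sqrt(v3), lower.tail = FALSE)
    } else {
      as.numeric(mu3 > bounds[3])
    },
    0
  )
  est <- 2 * p1 * mean(g)
  se <- 2 * p1 * stats::sd(g) / sqrt(n_draw)
  list(rate = est, se = se)
}

# A small pool of random but reproducible designs.
random_designs <- function(k, seed, lo = 50, hi = 50000) {
  set.seed(seed)
  matrix(sample(lo:hi, 4 * k, replace = TRUE), ncol = 4,
         dimnames = list(NULL, c("n0", "n1", "n0p", "n1p")))
}
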