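test_that("independent statistics give the closed-form joint null rate", {
  # hypothetical uncorrelated triple: 2 (a/2)(b/2)(g/2) = abg/4
  a <- 1e-3
  b <- 1e-2
  g <- 1e-4
  lo <- -qnorm(c(a, b, g) / 2)
  expect_equal(2 * mvn_tail(diag(3), lo), a * b * g / 4, tolerance = 1e-9)
})

test_that("gamma = 1 zeroes the meta-analytic bound", {
  des <- study_design(15000, 5000, 5000, 5000)
  r1 <- null_hit_rate(des, 1e-4, 1e-3, 1, "A")
  S <- covariance_matrix(des, "A")
  r2 <- 2 * mvn_tail(S, c(-qnorm(5e-5), -qnorm(5e-4), 0))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("null hit rate matches the conditioned Monte-Carlo oracle", {
  des <- study_design(20169, 5539, 8806, 6768)
  a <- 5e-6
  b <- 5e-4
  g <- 5e-8
  r <- null_hit_rate(des, a, b, g, "A")
  o <- mc_hit_rate_cond(covariance_matrix(des, "A"),
                        -qnorm(c(a, b, g) / 2), n_draw = 4e5, seed = 11)
  expect_lt(abs(r - o$rate), 4 * o$se)
})

test_that("solved thresholds conserve the null hit rate and are ordered", {
  des_list <- random_designs(12, seed = 202, lo = 500, hi = 40000)
  set.seed(203)
  for (i in seq_len(nrow(des_list))) {
    n <- des_list[i, ]
    des <- study_design(n[1], n[2], n[3], n[4])
    a <- 10^runif(1, -7, -3)
    b <- 10^runif(1, -4, -1.2)
    g <- 10^runif(1, -9, -4)
    adj <- adjust_thresholds(des, a, b, g)
    # strict ordering beta_perp < beta_star < beta
    expect_lt(adj$beta_perp, adj$beta_star)
    expect_lt(adj$beta_star, adj$beta)
    # conservation to 1e-12 on the probability scale
    expect_lt(abs(null_hit_rate(des, a, adj$beta_star, g, "B") - adj$p0),
              1e-12)
    expect_lt(abs(null_hit_rate(des, a, adj$beta_perp, g, "C") - adj$p0),
              1e-12)
    expect_lt(max(adj$residual), 1e-12)
  }
})

test_that("conservation of the shared-control rate holds empirically", {
  # dual route: conditioned MC of the method-B rate at the solved beta*
  des <- study_design(15000, 5000, 5000, 5000)
  a <- 5e-6
  b <- 5e-4
  g <- 5e-8
  adj <- adjust_thresholds(des, a, b, g)
  oa <- mc_hit_rate_cond(covariance_matrix(des, "A"),
                         -qnorm(c(a, b, g) / 2), n_draw = 4e5, seed = 21)
  ob <- mc_hit_rate_cond(covariance_matrix(des, "B"),
                         c(-qnorm(a / 2), adj$z_beta_star, -qnorm(g / 2)),
                         n_draw = 4e5, seed = 22)
  expect_lt(abs(oa$rate - ob$rate), 4 * sqrt(oa$se^2 + ob$se^2))
})

test_that("beta* approaches beta as the sharing correlation vanishes", {
  # huge independent replication-control pool: rho_ds ~ 0
  des <- study_design(200, 5000, 500000, 5000)
  adj <- adjust_thresholds(des, 1e-4, 1e-3, 1e-6)
  expect_lt(shared_correlations(des)$rho_ds, 0.02)
  expect_gt(adj$beta_star / adj$beta, 0.93)
})

test_that("beta* is non-increasing in the sharing correlation", {
  bs <- vapply(c(2000, 6000, 20000, 60000), function(n0p) {
    des <- study_design(12000, 4000, n0p, 4000)
    adjust_thresholds(des, 5e-6, 5e-4, 5e-8)$beta_star
  }, numeric(1))
  # rho_ds decreases with n0p, so beta* must increase along this sequence
  expect_true(all(diff(bs) > 0))
})

test_that("asymptotic form is approached from above in the gamma = 1 regime", {
  des <- study_design(15000, 5000, 5000, 5000)
  b <- 5e-4
  ratios <- vapply(c(6, 7, 8), function(za) {
    a <- 2 * pnorm(za, lower.tail = FALSE)
    adj <- adjust_thresholds(des, a, b, 1)
    adj$z_beta_star / asymptotic_beta_star(des, a, b, "B")
  }, numeric(1))
  expect_true(all(ratios >= 1))
  expect_true(all(diff(ratios) < 0))    # converging towards 1
  expect_lt(ratios[3] - 1, 0.01)        # within 1% at z_alpha = 8
  # and the solved threshold always exceeds both anchors in this regime
  a <- 2 * pnorm(6, lower.tail = FALSE)
  adj <- adjust_thresholds(des, a, b, 1)
  expect_gte(adj$z_beta_star,
             max(-qnorm(b / 2), asymptotic_beta_star(des, a, b, "B")))
  expect_equal(asymptotic_beta_star(study_design(200, 5000, 500000, 5000),
                                    1e-4, b, "B"),
               -qnorm(b / 2), tolerance = 2e-2)
})

test_that("gamma = 1 conventions: nondirectional conserves alpha*beta and
           coincides with beta when the statistics are independent", {
  # near-independent: rho_ds ~ 0
  des0 <- study_design(200, 5000, 500000, 5000)
  nd <- adjust_thresholds(des0, 1e-3, 1e-2, 1, convention = "nondirectional")
  expect_equal(nd$p0, 1e-3 * 1e-2, tolerance = 1e-12)
  expect_equal(nd$beta_star, 1e-2, tolerance = 1e-3)
  # correlated design: the two conventions genuinely differ
  des <- study_design(15000, 5000, 5000, 5000)
  di <- adjust_thresholds(des, 1e-3, 1e-2, 1, convention = "directional")
  nd <- adjust_thresholds(des, 1e-3, 1e-2, 1, convention = "nondirectional")
  expect_gt(abs(di$beta_star - nd$beta_star) / nd$beta_star, 1e-3)
  # nondirectional solution against a bivariate MC oracle
  set.seed(31)
  rho <- shared_correlations(des)$rho_ds
  z <- matrix(rnorm(2e6), ncol = 2)
  z2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  za <- -qnorm(1e-3 / 2)
  hit <- abs(z[, 1]) > za & abs(z2) > nd$z_beta_star
  expect_lt(abs(mean(hit) - 1e-3 * 1e-2),
            4 * sqrt(mean(hit) / 2e6) + 1e-7)
})

test_that("degenerate threshold systems fail loudly", {
  des <- study_design(5000, 5000, 5000, 5000)
  expect_error(adjust_thresholds(des, 5e-6, 1, 5e-8), "beta must lie")
  expect_error(null_hit_rate(des, 0, 5e-4, 5e-8, "A"), "alpha, beta, gamma")
})

test_that("tidy and glance expose the solved quantities", {
  des <- study_design(4308, 2154, 5094, 1372)
  adj <- adjust_thresholds(des, 1e-4, 1e-3, 5e-8)
  td <- tidy(adj)
  expect_equal(td$term, c("p0", "beta_star", "beta_perp"))
  expect_equal(td$estimate[2], adj$beta_star)
  gl <- glance(adj)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$beta_perp, adj$beta_perp)
  expect_equal(gl$n0, 4308)
})
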