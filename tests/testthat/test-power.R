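ftd_design <- function() study_design(4308, 2154, 5094, 1372)

test_that("zero noncentrality reduces every method to the conserved P0", {
  des <- ftd_design()
  adj <- adjust_thresholds(des, 1e-4, 1e-3, 5e-8)
  z0 <- zeta_for_scenario(des, character(0), 0)
  for (m in c("A", "B", "C")) {
    expect_equal(rejection_probability(des, adj, z0, m), adj$p0,
                 tolerance = 1e-10)
  }
})

test_that("power saturates at extreme effects", {
  des <- ftd_design()
  adj <- adjust_thresholds(des, 1e-4, 1e-3, 5e-8)
  big <- tibble::tibble(zeta_d = 40, zeta_r = 40, zeta_s = 40,
                        zeta_c = 40, zeta_m = 40)
  for (m in c("A", "B", "C")) {
    expect_gt(rejection_probability(des, adj, big, m), 1 - 1e-6)
  }
})

test_that("power curve endpoints behave and the usual ordering holds on a
           shared-control-favourable design", {
  des <- study_design(15000, 5000, 5000, 5000)
  adj <- adjust_thresholds(des, 5e-6, 5e-4, 5e-8)
  pc <- power_curve(des, adj, 0.1, c(0, 0.2, 3))
  wide <- tidyr::pivot_wider(pc, names_from = "method",
                             values_from = "power")
  # null effect: all methods at P0; huge effect: all near 1
  expect_true(all(abs(unlist(wide[1, c("A", "B", "C")]) - adj$p0) < 1e-10))
  expect_true(all(unlist(wide[3, c("A", "B", "C")]) > 1 - 1e-6))
  # moderate effect: C >= B >= A on this design
  expect_gt(wide$B[2], wide$A[2])
  expect_gte(wide$C[2], wide$B[2])
})

test_that("average power difference is zero for identical methods and
           matches the frozen trapezoid oracle for B vs A", {
  des <- study_design(5000, 5000, 5000, 5000)
  adj <- adjust_thresholds(des, 5e-6, 5e-4, 5e-8)
  expect_equal(average_power_difference(des, adj, 0.1, "A", "A")$integral, 0)
  # frozen oracle: 2001-point trapezoid over log-OR in [-1.5, 1.5] gives
  # -0.00472149 for this balanced design (B is weaker on average here)
  avg <- average_power_difference(des, adj, 0.1, "B", "A")
  expect_equal(avg$integral, -0.00472149, tolerance = 1e-4)
  expect_equal(avg$mean_difference, avg$integral / (2 * avg$window))
})

test_that("maximum power difference locates a positive advantage for a
           control-rich discovery design", {
  des <- study_design(15000, 5000, 5000, 5000)
  adj <- adjust_thresholds(des, 5e-6, 5e-4, 5e-8)
  mx <- max_power_difference(des, adj, 0.1, n_grid = 101)
  expect_gt(mx$max_difference, 0.05)
  # the difference profile is close to even in the log-odds ratio, so the
  # peak may sit on either side; it must be interior to the window
  expect_lt(abs(mx$at_log_or), 16)
  mirror <- function(x) {
    spec <- freqs_from_or(des, x, 0.1)
    z <- noncentralities(des, spec)
    rejection_probability(des, adj, z, "B") -
      rejection_probability(des, adj, z, "A")
  }
  expect_equal(mirror(-mx$at_log_or), mx$max_difference, tolerance = 0.15)
  expect_equal(max_power_difference(des, adj, 0.1, "A", "A")$max_difference,
               0)
})

test_that("controls-for-parity satisfies its bisection contract", {
  des <- study_design(15000, 5000, 5000, 5000)
  adj <- adjust_thresholds(des, 5e-6, 5e-4, 5e-8)
  res <- controls_for_parity(des, adj, 0.1, log_or = 0.2)
  expect_true(res$reached_parity)
  expect_gt(res$additional_controls, 0)
  expect_gte(res$power_A_at, res$power_B)
  # one control fewer must fall short
  d <- as.list(des)
  des_minus <- study_design(d$n0, d$n1, d$n0p + res$additional_controls - 1,
                            d$n1p)
  spec <- freqs_from_or(des_minus, 0.2, 0.1)
  pa <- rejection_probability(des_minus, adj,
                              noncentralities(des_minus, spec), "A")
  expect_lt(pa, res$power_B)
  # parity already reached returns zero
  same <- controls_for_parity(des, adj, 0.1, log_or = 0.2, cap = 10)
  expect_false(same$reached_parity)
  expect_equal(same$additional_controls, 10L)
})

test_that("error profiles start at P0 and approach the analytic limits", {
  des <- ftd_design()
  adj <- adjust_thresholds(des, 1e-4, 1e-3, 5e-8)
  prof <- type1_profile(des, adj, "C1", c(0, 20))
  at0 <- prof[prof$zeta == 0, ]
  expect_true(all(abs(at0$rate - adj$p0) < 1e-10))
  at20 <- prof[prof$zeta == 20, ]
  # aberrance confined to discovery cases: limits beta/2, beta*/2, beta'/2
  expect_equal(at20$rate[at20$method == "A"], adj$beta / 2,
               tolerance = 1e-4)
  expect_equal(at20$rate[at20$method == "B"], adj$beta_star / 2,
               tolerance = 1e-4)
  expect_equal(at20$rate[at20$method == "C"], adj$beta_perp / 2,
               tolerance = 1e-4)
  # aberrance in replication cases: all rates approach alpha/2
  prof2 <- type1_profile(des, adj, "C1p", c(20))
  expect_true(all(abs(prof2$rate - adj$alpha / 2) / (adj$alpha / 2) < 1e-3))
})

test_that("rate bounds by aberrant cohort hold along the whole profile", {
  des <- study_design(9000, 3000, 5000, 2500)
  adj <- adjust_thresholds(des, 1e-4, 1e-3, 5e-8)
  grid <- c(0, 0.5, 1, 2, 4, 8, 16)
  bounds <- list(
    C1  = c(A = adj$beta, B = adj$beta_star, C = adj$beta_perp),
    C1p = c(A = adj$alpha, B = adj$alpha, C = adj$alpha),
    C0p = c(A = adj$alpha, B = adj$alpha, C = 1),
    C0  = c(A = adj$beta, B = 1, C = 1)
  )
  for (sc in names(bounds)) {
    prof <- type1_profile(des, adj, sc, grid)
    for (m in c("A", "B", "C")) {
      expect_lt(max(prof$rate[prof$method == m]), bounds[[sc]][[m]] + 1e-9)
    }
  }
  # shared controls reduce the error under replication-control aberrance
  prof0p <- type1_profile(des, adj, "C0p", grid, methods = c("A", "B"))
  ra <- prof0p$rate[prof0p$method == "A"]
  rb <- prof0p$rate[prof0p$method == "B"]
  expect_true(all(rb <= ra + 1e-12))
})

test_that("opposite-direction aberrance in the two case cohorts lowers the
           error below the single-cohort scenario", {
  des <- study_design(9000, 3000, 5000, 2500)
  adj <- adjust_thresholds(des, 1e-4, 1e-3, 5e-8)
  single <- type1_profile(des, adj, "C1", c(2, 4), methods = "A")
  both <- type1_profile(des, adj, c("C1", "C1p"), c(2, 4),
                        weights = c(1, -1), driving = "zeta_d",
                        methods = "A")
  expect_true(all(both$rate < single$rate))
})

test_that("analytic error-difference bound evaluates the printed k factors
           and stays far below alpha/2", {
  bal <- study_design(3000, 3000, 3000, 3000)
  expect_equal(rb_ra_bound(bal, 5e-6, 5e-4, "C1p")$k, sqrt(4 / 3),
               tolerance = 1e-12)
  expect_equal(rb_ra_bound(bal, 5e-6, 5e-4, "C0p")$k, sqrt(1 / 3),
               tolerance = 1e-12)
  b <- rb_ra_bound(study_design(20169, 5539, 8806, 6768), 5e-6, 5e-4, "C1p")
  expect_gt(b$bound, 0)
  expect_lt(b$bound, 5e-6 / 2)
})

test_that("autoplot methods return ggplot objects", {
  des <- study_design(2000, 2000, 2000, 2000)
  adj <- adjust_thresholds(des, 1e-4, 1e-3, 1e-6)
  pc <- power_curve(des, adj, 0.1, c(0.1, 0.3), methods = c("A", "B"))
  expect_s3_class(ggplot2::autoplot(pc), "ggplot")
  prof <- type1_profile(des, adj, "C1", c(0, 1), methods = c("A", "B"))
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
})
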