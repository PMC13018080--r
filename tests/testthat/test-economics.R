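make_flat_traj <- function(independent, dependent, dead, horizon = 30,
                           occ = 0) {
  grid <- time_grid(horizon)
  data.frame(stratum = "ci", time_years = grid,
             f_independent = independent, f_dependent = dependent,
             f_dead = dead, nh_occupancy = occ)
}

test_that("acute cost returns the stratum constant for every admitted patient", {
  cs <- cfg_default$costs
  expect_equal(acute_cost("ci", cs), 122200.96)
  expect_equal(acute_cost("no_ci", cs), 89997.00)
  cs0 <- cs; cs0$acute_with_ci <- 0
  expect_equal(acute_cost("ci", cs0), 0)
  expect_error(acute_cost("with_infarct", cs), "stratum")
})

test_that("point QALYs are the cross-sectional utility mix, monotone in independence", {
  u <- cfg_default$utilities
  expect_equal(point_qaly(state_distribution(1, 0, 0), u, 100), 74.0)
  expect_equal(point_qaly(state_distribution(0, 0, 1), u, 100), 0)
  # monotone in f_independent at fixed f_dead
  q <- sapply(seq(0, 0.7, by = 0.1), function(fi)
    point_qaly(state_distribution(fi, 0.7 - fi, 0.3), u, 100))
  expect_true(all(diff(q) > 0))
})

test_that("first-year disability cost applies annual band rates to the 1-year mix", {
  cs <- cfg_default$costs
  tr <- make_flat_traj(1, 0, 0)
  expect_equal(disability_cost(tr, cs, c(0, 1), n = 100), 1429380.00)
  expect_equal(disability_cost(make_flat_traj(0, 1, 0), cs, c(0, 1), n = 10),
               156333.00)
  expect_equal(disability_cost(make_flat_traj(0, 0, 1), cs, c(0, 30), n = 100), 0)
})

test_that("years-2-to-5 block is the 1.33-expanded sum of the three evaluations", {
  cs <- cfg_default$costs
  tr <- make_flat_traj(1, 0, 0)
  expect_equal(disability_cost(tr, cs, c(1, 5), n = 1),
               1.33 * 3 * cs$annual_mrs02)
  expect_equal(disability_cost(tr, cs, c(0, 5), n = 1),
               cs$annual_mrs02 * (1 + 1.33 * 3))
  # post-5y block: constant annual application to survivors
  expect_equal(disability_cost(tr, cs, c(5, 30), n = 1),
               25 * cs$annual_mrs02)
  expect_error(disability_cost(make_flat_traj(1, 0, 0, horizon = 5), cs,
                               c(0, 10)), "beyond")
  expect_error(disability_cost(tr, cs, c(0.5, 2)), "start")
})

test_that("nursing-home cost applies the 0.85 first-year and 1.33 block factors", {
  cs <- cfg_default$costs
  tr <- make_flat_traj(0.5, 0.3, 0.2, occ = 0.10)
  expect_equal(nursing_home_cost(tr, cs, c(0, 1), n = 100),
               10 * 114665 * 0.85)  # 974,652.50
  expect_equal(nursing_home_cost(tr, cs, c(0, 1), n = 100), 974652.50)
  cs1 <- cs; cs1$nh_firstyear_factor <- 1
  expect_equal(nursing_home_cost(make_flat_traj(0.5, 0.3, 0.2, occ = 0.01),
                                 cs1, c(0, 1), n = 100), 114665.00)
  expect_equal(nursing_home_cost(make_flat_traj(1, 0, 0, occ = 0), cs,
                                 c(0, 30), n = 100), 0)
  expect_equal(nursing_home_cost(tr, cs, c(1, 5), n = 1),
               1.33 * 114665 * 0.30)
  tr_bad <- make_flat_traj(0.5, 0.3, 0.2, occ = -0.1)
  expect_error(nursing_home_cost(tr_bad, cs, c(0, 1)), "negative")
})

test_that("anchor-mode base-case totals reproduce the published aggregates", {
  st <- scenario_totals(cfg_default, p = 0.35, horizon = 1)
  expect_equal(st$ci_cost, 5982964)
  expect_equal(st$no_ci_cost, 7794976)
  expect_equal(st$total_cost, 13777940)
  expect_equal(st$total_qaly, 56.9)
  st5 <- scenario_totals(cfg_default, p = 0.35, horizon = 5)
  expect_equal(st5$total_cost, 21833504.20)
  expect_equal(st5$total_qaly, 56.1)
  st30 <- scenario_totals(cfg_default, p = 0.35, horizon = 30)
  expect_equal(st30$total_cost, 60914997.20)
  expect_equal(st30$total_qaly, 18.28, tolerance = 1e-9)
})

test_that("anchor-mode 1-year totals are affine in the infarction proportion", {
  pp <- calibrate_anchors(cfg_default$anchors)
  c_ci <- pp$cost_per_patient[pp$stratum == "ci" & pp$horizon == 1]
  c_no <- pp$cost_per_patient[pp$stratum == "no_ci" & pp$horizon == 1]
  for (p in c(0, 0.1, 0.2, 0.35, 0.5, 1)) {
    st <- scenario_totals(cfg_default, p = p, horizon = 1)
    expect_equal(st$total_cost, 100 * (p * c_ci + (1 - p) * c_no),
                 tolerance = 1e-9)
  }
  # degenerate single-stratum mixture
  st0 <- scenario_totals(cfg_default, p = 0, horizon = 1)
  expect_equal(st0$total_cost, 100 * c_no)
  expect_equal(st0$total_qaly, 100 * 0.66)
})

test_that("published 5- and 30-year scenario cells are served verbatim", {
  st <- scenario_totals(cfg_default, p = 0.25, horizon = 5)
  expect_equal(st$total_cost, 20976797)
  expect_equal(st$total_qaly, 57.9)
  st30 <- scenario_totals(cfg_default, p = 0.20, horizon = 30)
  expect_equal(st30$total_cost, 61177403)
  expect_true(is.na(st$ci_cost))
  expect_error(scenario_totals(cfg_default, p = 0.17, horizon = 5),
               "mechanistic")
})

test_that("anchor back-solution divides stratum totals by stratum size", {
  pp <- calibrate_anchors(cfg_default$anchors)
  expect_equal(pp$cost_per_patient[pp$stratum == "ci" & pp$horizon == 1],
               5982964 / 35)  # 170,941.83; printed rounded 170,941.80
  expect_equal(pp$qaly_per_patient[pp$stratum == "no_ci" & pp$horizon == 1],
               42.9 / 65)     # 0.66
  expect_equal(attr(pp, "identity_residual"), 0.20, tolerance = 1e-6)

  # perturbing a 1-year anchor leaves the (5y/30y-only) identity intact and
  # shifts the per-patient value by the expected amount
  a2 <- cfg_default$anchors
  a2$ci$cost_1y <- a2$ci$cost_1y + 1e6
  pp2 <- calibrate_anchors(a2)
  expect_equal(pp2$cost_per_patient[pp2$stratum == "ci" & pp2$horizon == 1] -
                 pp$cost_per_patient[pp$stratum == "ci" & pp$horizon == 1],
               1e6 / 35)
  # violating the identity is a calibration error
  a3 <- cfg_default$anchors
  a3$no_ci$cost_5to30 <- a3$no_ci$cost_5to30 + 100
  expect_error(calibrate_anchors(a3), "identity")
})

test_that("cumulative cost is non-decreasing in the horizon (mechanistic)", {
  for (s in c("ci", "no_ci")) {
    costs <- sapply(c(1, 5, 10, 20, 30),
                    function(h) stratum_outcome(cfg_default, s, h)$cost)
    expect_true(all(diff(costs) > 0))
  }
})

test_that("mechanistic totals honour the documented calibration residuals", {
  res <- mechanistic_residuals(cfg_default)
  ci <- res[res$stratum == "ci", ]
  expect_true(all(abs(ci$cost_residual) < 50))
  no <- res[res$stratum == "no_ci", ]
  expect_lt(abs(no$cost_residual[no$horizon == 1]), 1)
  # structural residuals of the no-infarction stratum (see methods vignette)
  expect_lt(abs(no$cost_residual[no$horizon == 5]), 8.2e5)
  expect_lt(abs(no$cost_residual[no$horizon == 30]), 4.5e5)
  expect_true(all(abs(res$qaly_residual) < 1e-6))
})

test_that("the calibration solver reproduces the frozen default schedule", {
  sch <- calibrate_schedule(cfg_default)
  for (s in c("ci", "no_ci")) {
    for (d in c("dist_3mo", "dist_1y", "dist_2y", "dist_3y", "dist_5y"))
      expect_equal(sch[[s]][[d]], cfg_default$schedule[[s]][[d]],
                   tolerance = 1e-4)
    expect_equal(sch[[s]]$mortality_post5y,
                 cfg_default$schedule[[s]]$mortality_post5y, tolerance = 1e-6)
    expect_equal(sch[[s]]$nh_3mo, cfg_default$schedule[[s]]$nh_3mo,
                 tolerance = 1e-4)
  }
})

test_that("scenario table covers the full proportion x horizon grid", {
  tab <- scenario_table(cfg_default)
  expect_equal(nrow(tab), 12)
  expect_equal(unique(tab$horizon), c(1, 5, 30))
  tab1 <- scenario_table(cfg_default, proportions = 0.35)
  expect_equal(nrow(tab1), 3)
})
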