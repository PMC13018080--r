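test_that("identity dynamics leave the distribution constant at every point", {
  traj <- simulate_cohort(cfg_static, horizon = 30)
  for (s in c("ci", "no_ci")) {
    tr <- traj[traj$stratum == s, ]
    d0 <- cfg_static$schedule[[s]]$dist_3mo
    expect_equal(tr$f_independent, rep(d0[["independent"]], nrow(tr)))
    expect_equal(tr$f_dependent, rep(d0[["dependent"]], nrow(tr)))
    expect_equal(tr$f_dead, rep(d0[["dead"]], nrow(tr)))
  }
})

test_that("saturating post-5y mortality absorbs everyone from year 6 onward", {
  cfg <- cfg_default
  cfg$schedule$ci$mortality_post5y <- 1
  tr <- simulate_cohort(cfg, horizon = 8, strata = "ci")
  expect_equal(tr$f_dead[tr$time_years >= 6], rep(1, 3))
  expect_equal(tr$nh_occupancy[tr$time_years >= 6], rep(0, 3))
})

test_that("default trajectories conserve mass, have monotone mortality, and plateau", {
  traj <- simulate_cohort(cfg_default, horizon = 30)
  for (s in c("ci", "no_ci")) {
    tr <- traj[traj$stratum == s, ]
    expect_equal(tr$f_independent + tr$f_dependent + tr$f_dead,
                 rep(1, nrow(tr)), tolerance = 1e-12)
    expect_true(all(diff(tr$f_dead) >= -1e-12))
    expect_true(all(tr$nh_occupancy <= 1 - tr$f_dead + 1e-12))
    # after year 5 the survivor mix is frozen
    post <- tr[tr$time_years >= 5, ]
    ratio_i <- post$f_independent / (1 - post$f_dead)
    ratio_d <- post$f_dependent / (1 - post$f_dead)
    expect_equal(ratio_i, rep(ratio_i[1], nrow(post)), tolerance = 1e-10)
    expect_equal(ratio_d, rep(ratio_d[1], nrow(post)), tolerance = 1e-10)
  }
})

test_that("calibrated 1-year point utility per patient matches the stratum anchors", {
  traj <- simulate_cohort(cfg_default, horizon = 1)
  at1 <- traj[traj$time_years == 1, ]
  u <- cfg_default$utilities
  q_ci <- point_qaly(c(independent = at1$f_independent[at1$stratum == "ci"],
                       dependent = at1$f_dependent[at1$stratum == "ci"],
                       dead = at1$f_dead[at1$stratum == "ci"]), u)
  expect_equal(q_ci, 0.400, tolerance = 1e-9)   # 14.0 QALYs / 35 patients
  q_no <- point_qaly(c(independent = at1$f_independent[at1$stratum == "no_ci"],
                       dependent = at1$f_dependent[at1$stratum == "no_ci"],
                       dead = at1$f_dead[at1$stratum == "no_ci"]), u)
  expect_equal(q_no, 0.660, tolerance = 1e-9)   # 42.9 QALYs / 65 patients
})

test_that("nursing-home retention arithmetic follows the printed schedule", {
  nhs <- cfg_default$nursing_home
  grid <- c(0.25, 1, 2, 3, 5)
  occ <- nursing_home_occupancy(0.10, nhs, grid)
  expect_equal(occ[1], 0.10)
  expect_equal(occ[2], 0.070)           # 0.10 * 0.70
  expect_equal(occ[3], 0.070 * 0.61)
  expect_equal(occ[5], 0.0252)          # 0.10 * 0.70 * 0.36
  # 3-year point interpolates geometrically between the 2y and 5y anchors
  expect_equal(occ[4], 0.070 * 0.61 * (0.36 / 0.61)^(1 / 3))
  expect_true(all(diff(occ[-1]) <= 1e-12))  # non-increasing after 1 year
  expect_equal(nursing_home_occupancy(0, nhs, grid), rep(0, 5))
  expect_error(nursing_home_occupancy(1.2, nhs, grid), "fraction")
})

test_that("post-5y occupancy rules behave as documented and respect survival", {
  grid <- time_grid(10)
  alive <- seq(0.9, 0.45, length.out = length(grid))
  nhs <- cfg_default$nursing_home

  occ_share <- nursing_home_occupancy(0.3, nhs, grid, alive = alive)
  post <- grid > 5
  expect_equal(occ_share[post], 0.13 * alive[post])

  nhs$post5y_mode <- "retain_all"
  occ_keep <- nursing_home_occupancy(0.3, nhs, grid, alive = alive)
  occ5 <- 0.3 * 0.70 * 0.36
  expect_equal(occ_keep[post], occ5 * alive[post] / alive[grid == 5])

  nhs$post5y_mode <- "retain_13pct"
  occ_decay <- nursing_home_occupancy(0.3, nhs, grid, alive = alive)
  expect_equal(occ_decay[post], occ5 * 0.13^(grid[post] - 5))
  expect_true(all(occ_decay <= alive + 1e-12))
})

test_that("trajectories equal independent matrix-power evolution", {
  set.seed(42)
  for (rep in 1:10) {
    d0 <- random_distribution()
    mats <- replicate(6, random_transition_matrix(), simplify = FALSE)
    expect_equal(evolve_states(d0, mats), matrix_power_evolution(d0, mats),
                 tolerance = 1e-12)
  }
})

test_that("transition matrices are validated (outflow, absorbing dead)", {
  bad <- matrix(c(0.7, 0.4, 0.2,
                  0.1, 0.8, 0.1,
                  0, 0, 1), nrow = 3, byrow = TRUE)
  expect_error(evolve_states(random_distribution(), list(bad)), "outflow")
  not_absorbing <- matrix(c(0.8, 0.1, 0.1,
                            0.1, 0.8, 0.1,
                            0.1, 0, 0.9), nrow = 3, byrow = TRUE)
  expect_error(evolve_states(random_distribution(), list(not_absorbing)),
               "absorbing")
})

test_that("transition_from_dists realizes arbitrary monotone-death moves", {
  set.seed(7)
  for (rep in 1:25) {
    from <- random_distribution()
    to <- random_distribution()
    if (to[["dead"]] < from[["dead"]]) { tmp <- from; from <- to; to <- tmp }
    M <- transition_from_dists(from, to)
    expect_equal(as.numeric(from %*% M), unname(to), tolerance = 1e-10)
  }
  expect_error(transition_from_dists(c(independent = 0.2, dependent = 0.3, dead = 0.5),
                                     c(independent = 0.5, dependent = 0.4, dead = 0.1)),
               "dead")
})

test_that("state distributions are validated", {
  expect_error(state_distribution(0.5, 0.6, 0.2), "sum")
  expect_error(state_distribution(-0.1, 0.9, 0.2), "\\[0, 1\\]")
  d <- state_distribution(0.5, 0.3, 0.2)
  expect_equal(sum(d), 1)
})
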