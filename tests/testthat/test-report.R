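test_that("scenario runner writes a byte-stable 12-row CSV", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  tab <- run_scenarios(cfg_default, out1, verbose = FALSE)
  expect_equal(nrow(tab), 12)
  run_scenarios(cfg_default, out2, verbose = FALSE)
  f1 <- file.path(out1, "scenarios.csv"); f2 <- file.path(out2, "scenarios.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  traj <- utils::read.csv(file.path(out1, "trajectories.csv"))
  expect_named(traj, c("time_years", "f_independent", "f_dependent",
                       "f_dead", "nh_occupancy", "stratum"))
  back <- utils::read.csv(f1)
  expect_equal(back$total_cost[back$p_infarction == 0.35 & back$horizon == 1],
               13777940)
})

test_that("ICER grid runner writes the grid and the figure series", {
  out <- withr::local_tempdir()
  tab <- run_icer_grid(cfg_default, out, verbose = FALSE)
  expect_equal(nrow(tab), 36)
  expect_true(file.exists(file.path(out, "icer_grid.csv")))
  series <- utils::read.csv(file.path(out, "icer_series.csv"))
  # one series point per grid cell plus the threshold levels
  expect_equal(nrow(series), 36 + 3)
  expect_true(all(cfg_default$wtp$thresholds %in%
                    series$icer[series$series == "wtp_threshold"]))
})

test_that("tornado and drugcost runners write their tables", {
  out <- withr::local_tempdir()
  tor <- run_tornado(cfg_default, out, verbose = FALSE)
  expect_true(file.exists(file.path(out, "tornado.csv")))
  expect_equal(tor$parameter[1], "nh_cost")
  tab <- run_drugcost(cfg_default, out, verbose = FALSE)
  expect_true(file.exists(file.path(out, "drug_costs.csv")))
  expect_equal(tab$total[tab$regimen == "cilostazol_200"], 3.64)
})

test_that("fixture generation is deterministic and emits valid configs", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  p1 <- generate_fixtures(out1, seed = 0)
  p2 <- generate_fixtures(out2, seed = 0)
  expect_equal(length(p1), 4)
  for (k in seq_along(p1))
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  # default fixture is the default config
  expect_equal(load_config(file.path(out1, "config-default.yaml")),
               default_config(), tolerance = 1e-12)
  # perturbed fixtures validate and drive the engine without error
  for (f in p1[-1]) {
    cfg <- load_config(f)
    st <- scenario_totals(cfg, p = 0.35, horizon = 1, mode = "mechanistic")
    expect_true(st$total_cost > 0)
    expect_true(st$total_qaly > 0 && st$total_qaly <= 74)
  }
  # different seed, different perturbations
  p3 <- generate_fixtures(withr::local_tempdir(), seed = 1)
  expect_false(identical(readLines(p1[2]), readLines(p3[2])))
})

test_that("the command-line interface reproduces the headline numbers", {
  skip_if_not(nzchar(Sys.which("Rscript")))
  cli <- system.file("cli", "sahcue.R", package = "sahcue")
  skip_if_not(nzchar(cli) && file.exists(cli))
  out <- withr::local_tempdir()
  # make sure the subprocess sees the library this package is loaded from
  withr::local_envvar(R_LIBS = paste(.libPaths(),
                                     collapse = .Platform$path.sep))
  status <- system2(Sys.which("Rscript"),
                    c(cli, "scenarios", "--out", shQuote(out), "--quiet"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  tab <- utils::read.csv(file.path(out, "scenarios.csv"))
  expect_equal(tab$total_cost[tab$p_infarction == 0.35 & tab$horizon == 1],
               13777940)
  status <- system2(Sys.which("Rscript"),
                    c(cli, "drugcost", "--out", shQuote(out), "--quiet"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  drugs <- utils::read.csv(file.path(out, "drug_costs.csv"))
  expect_equal(drugs$total[drugs$regimen == "albumin_x7"], 3128.72)
  status <- system2(Sys.which("Rscript"),
                    c(cli, "icer-grid", "--horizons", "5", "--out",
                      shQuote(out), "--quiet"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  g <- utils::read.csv(file.path(out, "icer_grid.csv"))
  expect_lt(abs(g$icer[g$reduction_pct == 15 & g$cost_per_patient == 5000] -
                  (-230904)), 3)
  status <- system2(Sys.which("Rscript"),
                    c(cli, "tornado", "--out", shQuote(out), "--quiet"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  tor <- utils::read.csv(file.path(out, "tornado.csv"))
  expect_lt(abs(tor$delta_high[tor$parameter == "qaly_gain"] - 20991), 2)
  expect_lt(abs(tor$delta_high[tor$parameter == "intervention_cost"] - 30303),
            2)
})
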