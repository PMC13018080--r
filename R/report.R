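#' Reporting, CSV export and fixture generation
#'
#' Thin wrappers that run the engine and write the standard tables as CSV:
#' the scenario table (costs and QALYs per proportion and horizon), the ICER
#' grid with WTP classes and the plot series behind the ICER-vs-cost
#' figures, the tornado table, and the drug-cost table. A fixture generator
#' emits the default configuration plus seeded random perturbations for
#' property testing. All outputs are deterministic for a fixed config and
#' seed. These functions are also the backend of the `sahcue` command-line
#' script (see `system.file("cli", "sahcue.R", package = "sahcue")`).
#'
#' @name cli_report
NULL

write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

log_line <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the scenario table and write it as CSV
#'
#' @param config validated config list.
#' @param out_dir output directory (created if needed).
#' @param proportions,horizons,mode passed to [scenario_table()].
#' @param verbose log one line per scenario evaluated.
#' @return The scenario data.frame, invisibly; writes `scenarios.csv`.
#' @export
run_scenarios <- function(config, out_dir = ".",
                          proportions = config$cohort$scenario_proportions,
                          horizons = c(1, 5, 30),
                          mode = c("anchor", "mechanistic"),
                          verbose = TRUE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- scenario_table(config, proportions, horizons, mode)
  for (k in seq_len(nrow(tab)))
    log_line(verbose, "scenario p=%.2f horizon=%sy mode=%s cost=%s qaly=%.1f",
             tab$p_infarction[k], tab$horizon[k], mode,
             format_dollar(tab$total_cost[k]), tab$total_qaly[k])
  write_csv_stable(tab, file.path(out_dir, "scenarios.csv"))
  traj <- simulate_cohort(config, horizon = max(horizons))
  write_csv_stable(traj[c("time_years", "f_independent", "f_dependent",
                          "f_dead", "nh_occupancy", "stratum")],
                   file.path(out_dir, "trajectories.csv"))
  invisible(tab)
}

#' Run the ICER grid, write the table and the plot series
#'
#' Writes `icer_grid.csv` (one row per horizon x reduction x intervention
#' cost, with ICER and WTP class) and `icer_series.csv`, the numeric series
#' behind the ICER-versus-intervention-cost figures (one series per
#' reduction and horizon, plus the WTP threshold levels), so the figures are
#' testable without image comparison. If ggplot2 is installed and
#' `plot = TRUE`, a PNG per horizon is also written.
#'
#' @param config validated config list.
#' @param out_dir output directory.
#' @param horizons,reductions_pct,costs_per_patient,mode see [icer_grid()].
#' @param plot write PNG figures when ggplot2 is available.
#' @param verbose log one line per grid row.
#' @return The grid data.frame, invisibly.
#' @export
run_icer_grid <- function(config, out_dir = ".", horizons = c(1, 5, 30),
                          reductions_pct = config$interventions$reductions_pct,
                          costs_per_patient = config$interventions$costs_per_patient,
                          mode = c("anchor", "mechanistic"),
                          plot = FALSE, verbose = TRUE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- icer_grid(config, horizons, reductions_pct, costs_per_patient,
                    mode = mode)
  for (k in seq_len(nrow(grid)))
    log_line(verbose, "icer horizon=%sy reduction=%s%% cost=%s icer=%s class=%s",
             grid$horizon[k], grid$reduction_pct[k],
             format_dollar(grid$cost_per_patient[k]),
             format_dollar(grid$icer[k]), grid$wtp_class[k])
  write_csv_stable(grid, file.path(out_dir, "icer_grid.csv"))
  series <- grid[c("horizon", "reduction_pct", "cost_per_patient", "icer")]
  thr <- data.frame(horizon = NA_real_, reduction_pct = NA_real_,
                    cost_per_patient = NA_real_,
                    icer = config$wtp$thresholds)
  thr$series <- "wtp_threshold"
  series$series <- sprintf("reduction_%s_pct", series$reduction_pct)
  write_csv_stable(rbind(series, thr),
                   file.path(out_dir, "icer_series.csv"))
  if (plot && requireNamespace("ggplot2", quietly = TRUE))
    plot_icer_figures(grid, config$wtp$thresholds, out_dir)
  invisible(grid)
}

plot_icer_figures <- function(grid, thresholds, out_dir) {
  for (h in unique(grid$horizon)) {
    g <- grid[grid$horizon == h, ]
    p <- ggplot2::ggplot(g, ggplot2::aes(
           x = .data$cost_per_patient, y = .data$icer,
           colour = factor(.data$reduction_pct))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed") +
      ggplot2::labs(x = "Intervention cost per patient (USD)",
                    y = "ICER (USD per QALY gained)",
                    colour = "Reduction (pct points)",
                    title = sprintf("ICER vs intervention cost, %s-year horizon", h))
    ggplot2::ggsave(file.path(out_dir, sprintf("icer_%sy.png", h)), p,
                    width = 7, height = 5, dpi = 150)
  }
}

#' Run the tornado analysis and write it as CSV
#'
#' @param config validated config list.
#' @param out_dir output directory.
#' @param anchor,mode,multipliers see [tornado_analysis()].
#' @param verbose log one line per sweep.
#' @return The tornado data.frame, invisibly; writes `tornado.csv`.
#' @export
run_tornado <- function(config, out_dir = ".",
                        anchor = default_anchor(config),
                        mode = c("anchor", "mechanistic"),
                        multipliers = list(), verbose = TRUE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- tornado_analysis(config, anchor = anchor, mode = mode,
                          multipliers = multipliers)
  for (k in seq_len(nrow(tab)))
    log_line(verbose, "tornado %s span=%s", tab$parameter[k],
             format_dollar(tab$span[k]))
  write_csv_stable(tab, file.path(out_dir, "tornado.csv"))
  invisible(tab)
}

#' Run the drug-cost table and write it as CSV
#'
#' @param config validated config list.
#' @param out_dir output directory.
#' @param verbose log one line per regimen.
#' @return The drug-cost data.frame, invisibly; writes `drug_costs.csv`.
#' @export
run_drugcost <- function(config, out_dir = ".", verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- drug_cost_table(config)
  for (k in seq_len(nrow(tab)))
    log_line(verbose, "drugcost %s total=%s", tab$regimen[k],
             format_dollar(tab$total[k], 2))
  write_csv_stable(tab, file.path(out_dir, "drug_costs.csv"))
  invisible(tab)
}

#' Generate configuration fixtures
#'
#' Writes (a) the package default configuration and (b) `n_perturbed` seeded
#' random perturbations in which unit costs are scaled by independent
#' U(0.8, 1.2) draws and utility weights are jittered within their ordering
#' bounds. Perturbed fixtures satisfy every structural invariant and are
#' meant for property tests; only the default fixture reproduces the
#' published numbers. Deterministic for a fixed seed.
#'
#' @param out_dir output directory.
#' @param seed integer RNG seed.
#' @param n_perturbed number of perturbed fixtures.
#' @return Character vector of file paths written, invisibly.
#' @export
generate_fixtures <- function(out_dir = ".", seed = 0, n_perturbed = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, "config-default.yaml")
  write_config(default_config(), paths)
  if (n_perturbed > 0) {
    rng <- local({ set.seed(seed); function(n, a, b) stats::runif(n, a, b) })
    for (k in seq_len(n_perturbed)) {
      cfg <- default_config()
      for (f in c("acute_with_ci", "acute_without_ci", "annual_mrs02",
                  "annual_mrs35", "nh_annual"))
        cfg$costs[[f]] <- cfg$costs[[f]] * rng(1, 0.8, 1.2)
      u_ind <- rng(1, 0.6, 0.9)
      cfg$utilities$independent <- u_ind
      cfg$utilities$dependent <- rng(1, 0.2, u_ind)
      p <- file.path(out_dir, sprintf("config-perturbed-%02d.yaml", k))
      write_config(cfg, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
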