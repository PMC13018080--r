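#' Costing and QALY accumulation
#'
#' Turns state trajectories into money and quality-adjusted life years.
#' The cost of a cohort over a horizon is the sum of: acute hospitalization
#' (all admitted patients, including those who die), post-hospitalization
#' disability care (annual rate by functional band, applied to alive
#' patient-years), and nursing-home residence (annual rate on the occupancy
#' series, additive on top of disability care). The first post-hospital year
#' uses the 1-year state distribution and the 3-month-seeded nursing-home
#' exposure with a 0.85 first-year discharge adjustment; years 2-5 are costed
#' at the three evaluated years (2, 3, 5) and expanded to the 4-year block by
#' the 1.33 multiplier; after year 5 annual rates apply unchanged to
#' survivors. QALYs are cross-sectional: the utility-weighted state mix at
#' the horizon time point, not an integral over time.
#'
#' @name economics
NULL

#' Acute hospitalization cost per patient
#'
#' @param stratum `"ci"` (with cerebral infarction) or `"no_ci"`.
#' @param costs the `costs` component of a config.
#' @return USD per admitted patient.
#' @export
#' @examples
#' acute_cost("ci", default_config()$costs)
acute_cost <- function(stratum, costs) {
  switch(match_stratum(stratum),
         ci = costs$acute_with_ci,
         no_ci = costs$acute_without_ci)
}

match_stratum <- function(stratum) {
  if (!is.character(stratum) || length(stratum) != 1 ||
      !stratum %in% c("ci", "no_ci"))
    fail("unknown stratum '%s' (use \"ci\" or \"no_ci\")",
         paste(stratum, collapse = ","))
  stratum
}

#' Point-in-time QALYs for a cohort
#'
#' `n * (f_independent * u_independent + f_dependent * u_dependent)`:
#' the utility-weighted state mix at one time point. Deliberately not an
#' aggregate of annual values.
#'
#' @param dist state distribution at the time point.
#' @param utilities the `utilities` config component.
#' @param n cohort size the distribution refers to.
#' @return QALYs (dimensionless).
#' @export
#' @examples
#' point_qaly(state_distribution(1, 0, 0), default_config()$utilities, 100)
point_qaly <- function(dist, utilities, n = 1) {
  d <- validate_state_distribution(dist)
  n * (d[["independent"]] * utilities$independent +
       d[["dependent"]] * utilities$dependent +
       d[["dead"]] * utilities$dead)
}

# Split a requested interval into the model's canonical cost blocks:
# [0,1] (first post-hospital year), [1,5] (the 1.33-expanded block),
# [5,t1] (constant annual costs on survivors).
split_blocks <- function(interval, horizon_max) {
  if (length(interval) != 2 || interval[2] <= interval[1])
    fail("interval must be c(t0, t1) with t1 > t0")
  t0 <- interval[1]; t1 <- interval[2]
  if (!t0 %in% c(0, 1, 5))
    fail("interval must start at 0, 1 or 5 years (got %s)", t0)
  if (!(t1 %in% c(1, 5) || (t1 > 5 && t1 == floor(t1) && t1 <= 30)))
    fail("interval must end at 1, 5 or a whole year in 6..30 (got %s)", t1)
  if (t1 > horizon_max + 1e-9)
    fail("interval [%s, %s] extends beyond the trajectory (max %s years)",
         t0, t1, horizon_max)
  blocks <- list()
  if (t0 == 0 && t1 >= 1) blocks <- c(blocks, list(c(0, 1)))
  if (t0 <= 1 && t1 >= 5) blocks <- c(blocks, list(c(1, 5)))
  if (t1 > 5) blocks <- c(blocks, list(c(5, t1)))
  blocks
}

traj_lookup <- function(traj, t) {
  i <- which(abs(traj$time_years - t) < 1e-9)
  if (!length(i)) fail("trajectory has no evaluation at %s years", t)
  traj[i[1L], ]
}

# discount factor hook; rate 0 (the default) leaves costs untouched
disc <- function(t, rate) if (rate > 0) (1 + rate)^(-t) else 1

#' Disability-care cost of a cohort over an interval
#'
#' Annual post-hospitalization care rates by functional band applied to the
#' trajectory per the model's block rules (see [economics]).
#'
#' @param traj single-stratum trajectory data.frame from [simulate_cohort()]
#'   (columns `time_years`, `f_independent`, `f_dependent`, `f_dead`).
#' @param costs the `costs` config component.
#' @param interval `c(t0, t1)` in years; must align with the block structure
#'   (start at 0, 1 or 5; end at 1, 5 or a whole year through 30).
#' @param n cohort size.
#' @return USD for the cohort over the interval.
#' @export
disability_cost <- function(traj, costs, interval, n = 1) {
  blocks <- split_blocks(interval, max(traj$time_years))
  rate <- costs$discount_rate %||% 0
  annual <- function(t) {
    r <- traj_lookup(traj, t)
    (r$f_independent * costs$annual_mrs02 +
     r$f_dependent * costs$annual_mrs35) * disc(t, rate)
  }
  total <- 0
  for (b in blocks) {
    if (b[1] == 0) total <- total + annual(1)
    else if (b[1] == 1)
      total <- total + costs$y2to5_multiplier * sum(vapply(c(2, 3, 5),
                                                           annual, numeric(1)))
    else total <- total + sum(vapply(6:b[2], annual, numeric(1)))
  }
  n * total
}

#' Nursing-home cost of a cohort over an interval
#'
#' The first-year exposure is the 3-month-seeded occupancy with the 0.85
#' discharge adjustment factor; years 2-5 are the evaluated occupancies at
#' 2, 3 and 5 years expanded by the 1.33 multiplier; after year 5 the annual
#' rate applies to the occupancy series directly. Additive on top of
#' [disability_cost()].
#'
#' @inheritParams disability_cost
#' @param traj single-stratum trajectory with an `nh_occupancy` column.
#' @return USD for the cohort over the interval.
#' @export
nursing_home_cost <- function(traj, costs, interval, n = 1) {
  if (any(traj$nh_occupancy < -1e-12))
    fail("nursing_home_cost: negative occupancy")
  blocks <- split_blocks(interval, max(traj$time_years))
  rate <- costs$discount_rate %||% 0
  occ <- function(t) traj_lookup(traj, t)$nh_occupancy
  total <- 0
  for (b in blocks) {
    if (b[1] == 0)
      total <- total + occ(0.25) * costs$nh_annual *
        costs$nh_firstyear_factor * disc(1, rate)
    else if (b[1] == 1)
      total <- total + costs$y2to5_multiplier * costs$nh_annual *
        sum(vapply(c(2, 3, 5), function(t) occ(t) * disc(t, rate), numeric(1)))
    else
      total <- total + costs$nh_annual *
        sum(vapply(6:b[2], function(t) occ(t) * disc(t, rate), numeric(1)))
  }
  n * total
}

#' Per-patient mechanistic cost and QALY for one stratum
#'
#' Runs the cohort model for one stratum and accumulates acute, disability
#' and nursing-home costs to the horizon, plus the point-in-time QALY there.
#'
#' @param config validated config list.
#' @param stratum `"ci"` or `"no_ci"`.
#' @param horizon 1, 5, or a whole year 6..30.
#' @return List with `cost` and `qaly`, both per patient.
#' @export
stratum_outcome <- function(config, stratum, horizon) {
  stratum <- match_stratum(stratum)
  if (!(horizon %in% c(1, 5) || (horizon > 5 && horizon <= 30 &&
                                 horizon == floor(horizon))))
    fail("horizon must be 1, 5 or a whole year in 6..30")
  traj <- simulate_cohort(config, horizon = max(horizon, 1), strata = stratum)
  cost <- acute_cost(stratum, config$costs) +
    disability_cost(traj, config$costs, c(0, horizon)) +
    nursing_home_cost(traj, config$costs, c(0, horizon))
  at_h <- traj_lookup(traj, horizon)
  qaly <- point_qaly(c(independent = at_h$f_independent,
                       dependent = at_h$f_dependent,
                       dead = at_h$f_dead), config$utilities)
  list(cost = cost, qaly = qaly)
}

#' Cohort totals for one infarction scenario at one horizon
#'
#' In anchor mode (the default) the per-patient stratum values come from the
#' published aggregate anchors; 1-year totals for any infarction proportion
#' `p` are the cohort mixture `n * (p * c_ci + (1 - p) * c_no_ci)` (and
#' likewise for QALYs); 5- and 30-year totals are the published scenario
#' cells for the standard proportions (they are not affine in `p`), with the
#' base case assembled from the stratum anchors (30-year = 5-year cumulative
#' plus the years-5-to-30 increments). In mechanistic mode all totals come
#' from [simulate_cohort()] and the cost operations, for any `p` and horizon.
#'
#' @param config validated config list.
#' @param p proportion of the cohort developing cerebral infarction.
#' @param horizon 1, 5 or 30 (anchor mode); any costing horizon
#'   (mechanistic mode).
#' @param mode `"anchor"` or `"mechanistic"`.
#' @return One-row data.frame: `mode`, `horizon`, `p_infarction`,
#'   `total_cost`, `total_qaly`, `ci_cost`, `no_ci_cost`, `ci_qaly`,
#'   `no_ci_qaly`. Stratum columns are `NA` for the stored published
#'   scenario cells, whose stratum split is not published.
#' @export
#' @examples
#' scenario_totals(default_config(), p = 0.35, horizon = 1)
scenario_totals <- function(config, p = config$cohort$p_infarction,
                            horizon = 1, mode = c("anchor", "mechanistic")) {
  mode <- match.arg(mode)
  if (p < 0 || p > 1) fail("p must be a fraction in [0, 1]")
  n <- config$cohort$n_patients
  if (mode == "mechanistic") {
    ci <- stratum_outcome(config, "ci", horizon)
    no <- stratum_outcome(config, "no_ci", horizon)
    return(scenario_row(mode, horizon, p,
                        ci_cost = n * p * ci$cost,
                        no_ci_cost = n * (1 - p) * no$cost,
                        ci_qaly = n * p * ci$qaly,
                        no_ci_qaly = n * (1 - p) * no$qaly))
  }
  a <- config$anchors
  pp <- calibrate_anchors(a)
  if (!horizon %in% c(1, 5, 30))
    fail("anchor mode supports horizons 1, 5 and 30 (got %s); use mechanistic mode",
         horizon)
  ppv <- function(s, col) pp[pp$stratum == s & pp$horizon == horizon, col]
  if (horizon == 1 || isTRUE(all.equal(p, config$cohort$p_infarction))) {
    return(scenario_row(mode, horizon, p,
                        ci_cost = n * p * ppv("ci", "cost_per_patient"),
                        no_ci_cost = n * (1 - p) * ppv("no_ci", "cost_per_patient"),
                        ci_qaly = n * p * ppv("ci", "qaly_per_patient"),
                        no_ci_qaly = n * (1 - p) * ppv("no_ci", "qaly_per_patient")))
  }
  key <- sprintf("p%03d", round(p * 100))
  cell <- a$table2[[key]]
  if (is.null(cell))
    fail(paste0("anchor mode has no published %s-year cell for p = %s; ",
                "supported proportions: %s (or use mechanistic mode)"),
         horizon, p, paste(config$cohort$scenario_proportions, collapse = ", "))
  cst <- if (horizon == 5) cell$cost_5y else cell$cost_30y
  qly <- if (horizon == 5) cell$qaly_5y else cell$qaly_30y
  out <- scenario_row(mode, horizon, p, NA_real_, NA_real_, NA_real_, NA_real_)
  out$total_cost <- cst
  out$total_qaly <- qly
  out
}

scenario_row <- function(mode, horizon, p, ci_cost, no_ci_cost,
                         ci_qaly, no_ci_qaly) {
  data.frame(mode = mode, horizon = horizon, p_infarction = p,
             total_cost = ci_cost + no_ci_cost,
             total_qaly = ci_qaly + no_ci_qaly,
             ci_cost = ci_cost, no_ci_cost = no_ci_cost,
             ci_qaly = ci_qaly, no_ci_qaly = no_ci_qaly)
}

#' Per-patient stratum values from the published aggregate anchors
#'
#' Back-solves per-patient cost and utility at each horizon as
#' `stratum_total / stratum_n`, after verifying the 30-year consistency
#' identity (5-year cohort total plus both years-5-to-30 increments must
#' equal the printed 30-year cohort total).
#'
#' @param anchors the `anchors` config component.
#' @param identity_tol allowed absolute violation (USD) of the 30-year
#'   identity before a calibration error is raised; default 5.
#' @return data.frame with columns `stratum`, `horizon` (1, 5, 30),
#'   `cost_per_patient` (cumulative from admission), `qaly_per_patient`.
#'   The verified identity residual is attached as attribute
#'   `identity_residual`.
#' @export
#' @examples
#' calibrate_anchors(default_config()$anchors)
calibrate_anchors <- function(anchors, identity_tol = 5) {
  lhs <- anchors$ci$cost_5y + anchors$no_ci$cost_5y +
    anchors$ci$cost_5to30 + anchors$no_ci$cost_5to30
  res <- lhs - anchors$printed_total_30y
  if (abs(res) > identity_tol)
    fail("calibration error: 30-year identity off by $%.2f (limit $%.2f)",
         res, identity_tol)
  one <- function(s) {
    a <- anchors[[s]]
    data.frame(
      stratum = s, horizon = c(1, 5, 30),
      cost_per_patient = c(a$cost_1y, a$cost_5y, a$cost_5y + a$cost_5to30) / a$n_strat,
      qaly_per_patient = c(a$qaly_1y, a$qaly_5y, a$qaly_30y) / a$n_strat)
  }
  out <- rbind(one("ci"), one("no_ci"))
  attr(out, "identity_residual") <- res
  out
}

#' Scenario table across proportions and horizons
#'
#' One row per (infarction proportion, horizon) with cohort costs and QALYs;
#' the reported-table layout of the engine.
#'
#' @param config validated config list.
#' @param proportions infarction proportions (default the standard scenarios).
#' @param horizons evaluation horizons (default 1, 5, 30).
#' @param mode `"anchor"` or `"mechanistic"`.
#' @return data.frame, rows ordered by horizon then decreasing proportion.
#' @export
scenario_table <- function(config,
                           proportions = config$cohort$scenario_proportions,
                           horizons = c(1, 5, 30),
                           mode = c("anchor", "mechanistic")) {
  mode <- match.arg(mode)
  rows <- lapply(horizons, function(h)
    do.call(rbind, lapply(proportions, function(p)
      scenario_totals(config, p = p, horizon = h, mode = mode))))
  do.call(rbind, rows)
}
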