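#' Model parameters: defaults, validation, config I/O
#'
#' Every constant the model uses lives in a single nested list ("config"):
#' cohort definition, utility weights by functional band, unit costs and
#' adjustment factors, the nursing-home retention schedule, willingness-to-pay
#' thresholds, the published aggregate anchors the engine is calibrated
#' against, the (calibrated) disability/mortality schedule, the intervention
#' grid, and the drug-regimen catalogue.
#'
#' @name parameters
NULL

#' Default model configuration
#'
#' Returns the full default parameter set. Monetary constants are 2025 US
#' dollars. The three-state disability/mortality schedule is a calibration
#' product (chosen so that the mechanistic cohort model reproduces the
#' published stratum-level cost/QALY anchors), not a literature reproduction;
#' it is flagged as such by `schedule$calibrated`.
#'
#' @return A named nested list with components `cohort`, `utilities`, `costs`,
#'   `nursing_home`, `wtp`, `anchors`, `schedule`, `interventions`, `drugs`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$costs$acute_with_ci
default_config <- function() {
  list(
    cohort = list(
      n_patients = 100L,
      p_infarction = 0.35,
      scenario_proportions = c(0.35, 0.30, 0.25, 0.20)
    ),
    utilities = list(
      independent = 0.74,  # utility/year, functionally independent (mRS 0-2)
      dependent   = 0.38,  # utility/year, functionally dependent (mRS 3-5)
      dead        = 0.0
    ),
    costs = list(
      acute_with_ci      = 122200.96, # USD/patient, acute stay, with cerebral infarction
      acute_without_ci   = 89997.00,  # USD/patient, acute stay, without cerebral infarction
      annual_mrs02       = 14293.80,  # USD/year, post-hospital care, mRS 0-2
      annual_mrs35       = 15633.30,  # USD/year, post-hospital care, mRS 3-5
      nh_annual          = 114665.00, # USD/year, nursing home residence
      nh_firstyear_factor = 0.85,     # discharge adjustment, 3 months -> 1 year
      y2to5_multiplier   = 1.33,      # 3 evaluated years (2,3,5) -> 4-year block
      discount_rate      = 0.0        # annual discount hook; model default is none
    ),
    nursing_home = list(
      retention_3mo_to_1y = 0.70,
      retention_1y_to_2y  = 0.61,
      retention_1y_to_5y  = 0.36,
      annual_rate_post5y  = 0.13,
      # post-5y occupancy rule: share_of_alive (13% of survivors reside in a
      # nursing home each year), retain_all (5-year occupancy carried forward,
      # deaths removed), retain_13pct (occupancy decays by factor 0.13/year)
      post5y_mode = "share_of_alive",
      utilization_3mo = list(mrs02 = 0.05, mrs35 = 0.75)
    ),
    wtp = list(thresholds = c(50000, 100000, 150000)), # strict "<" comparison
    anchors = sahcue_default_anchors(),
    schedule = sahcue_default_schedule(),
    interventions = list(
      costs_per_patient = c(5000, 10000, 15000, 20000),
      reductions_pct = c(5, 10, 15)
    ),
    drugs = sahcue_default_drugs()
  )
}

# Published aggregate cost/QALY anchors per stratum and horizon.
# 1y and 5y stratum costs are cumulative from admission; the 30-year stratum
# cost figures are the years-5-to-30 increments (the only reading under which
# 5y total + both increments equals the printed 30-year cohort total).
sahcue_default_anchors <- function() {
  list(
    ci = list(
      n_strat = 35L,
      cost_1y = 5982964, qaly_1y = 14.0,
      cost_5y = 9529902.30, qaly_5y = 13.5,
      cost_5to30 = 10112038, qaly_30y = 3.08
    ),
    no_ci = list(
      n_strat = 65L,
      cost_1y = 7794976, qaly_1y = 42.9,
      cost_5y = 12303601.90, qaly_5y = 42.6,
      cost_5to30 = 28969455, qaly_30y = 15.2
    ),
    printed_total_30y = 60914997,
    # Published 5- and 30-year scenario cells for the reduced infarction
    # proportions. These are not affine in the infarction proportion and are
    # therefore stored verbatim rather than recomposed.
    table2 = list(
      p030 = list(cost_5y = 21371192,    qaly_5y = 56.8,
                  cost_30y = 60546080,   qaly_30y = 18.8),
      p025 = list(cost_5y = 20976797,    qaly_5y = 57.9,
                  cost_30y = 61075366,   qaly_30y = 19.5),
      p020 = list(cost_5y = 20571518.30, qaly_5y = 59.4,
                  cost_30y = 61177403,   qaly_30y = 20.2)
    )
  )
}

# Calibrated three-state schedule: the frozen output of calibrate_schedule()
# at the default anchors. These are calibration products, not literature
# values; the methods vignette discusses the artifacts this entails.
sahcue_default_schedule <- function() {
  dist <- function(i, d) c(independent = i, dependent = d, dead = 1 - i - d)
  list(
    calibrated = TRUE,
    ci = list(
      dist_3mo = dist(0.5611346990, 0.4213335780),  # dead 0.0175317230
      dist_1y  = dist(0.0773269763, 0.9020474671),  # dead 0.0206255566
      dist_2y  = dist(0.1155645681, 0.6621427167),  # dead 0.2222927152
      dist_3y  = dist(0.1676479880, 0.6005426068),  # dead 0.2318094052
      dist_5y  = dist(0.2710801593, 0.4871446522),  # dead 0.2417751885
      mortality_post5y = 0.0573973033,
      nh_3mo = 0.3440569184
    ),
    no_ci = list(
      dist_3mo = dist(0.8466709413, 0.1533290587),  # dead 0
      dist_1y  = dist(0.7777777778, 0.2222222222),  # dead 0
      dist_2y  = dist(0.7668407509, 0.2089550442),  # dead 0.0242042049
      dist_3y  = dist(0.7747292166, 0.2010665784),  # dead 0.0242042050
      dist_5y  = dist(0.7905061481, 0.1852896468),  # dead 0.0242042051
      mortality_post5y = 0.0403842672,
      nh_3mo = 0.1573303411
    )
  )
}

# Drug-regimen catalogue (NADAC/AWP 2025 unit costs and fixed schedules).
sahcue_default_drugs <- function() {
  list(
    regimens = list(
      cilostazol_200 = list(
        label = "Cilostazol 100 mg tablet (200 mg/d x 14 days)",
        unit_cost = 0.13, units_per_day = 2, duration_days = 14),
      cilostazol_300 = list(
        label = "Cilostazol 100 mg tablet (300 mg/d x 14 days)",
        unit_cost = 0.13, units_per_day = 3, duration_days = 14),
      albumin_x1 = list(
        label = "IV 25% humanized albumin (1.25 g/kg dose x 1 dose)",
        albumin = TRUE, bag_cost = 55.87, dose_g_per_kg = 1.25,
        weight_kg = 80, bag_g = 12.5, n_doses = 1),
      albumin_x7 = list(
        label = "IV 25% humanized albumin (1.25 g/kg dose x 7 doses)",
        albumin = TRUE, bag_cost = 55.87, dose_g_per_kg = 1.25,
        weight_kg = 80, bag_g = 12.5, n_doses = 7),
      nimodipine = list(
        label = "Nimodipine 30 mg capsules (60 mg q4h) x 21 days",
        unit_cost = 1.09, units_per_day = 12, duration_days = 21)
    ),
    combos = list(
      cilostazol200_albumin1 = c("cilostazol_200", "albumin_x1"),
      cilostazol200_albumin1_nimodipine =
        c("cilostazol_200", "albumin_x1", "nimodipine"),
      cilostazol300_albumin7 = c("cilostazol_300", "albumin_x7")
    ),
    clazosentan = list(
      label = "IV Clazosentan", jpy = 2215691,
      usd_2023 = 15332.03, usd_2025 = 16280.15
    )
  )
}

#' Validate a model configuration
#'
#' Checks every structural invariant the engine relies on: utility ordering
#' 0 <= dead <= dependent <= independent <= 1, non-negative monetary inputs,
#' positive adjustment factors, nursing-home fractions in \[0, 1\] with
#' 5-year retention not exceeding 2-year retention, strictly increasing
#' positive WTP thresholds, a valid cohort definition, state distributions
#' that are non-negative and sum to one, and the 30-year anchor consistency
#' identity (5-year cohort total plus both 5-to-30-year increments must equal
#' the printed 30-year total within a small slack).
#'
#' @param config a config list as returned by [default_config()].
#' @param identity_tol allowed absolute discrepancy (USD) in the 30-year
#'   anchor identity; default 5.
#' @return `config`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_config <- function(config, identity_tol = 5) {
  u <- config$utilities
  if (!(u$dead >= 0 && u$dead <= u$dependent &&
        u$dependent <= u$independent && u$independent <= 1))
    fail("utilities: need 0 <= dead <= dependent <= independent <= 1 (got %s/%s/%s)",
         u$dead, u$dependent, u$independent)

  cs <- config$costs
  money <- c("acute_with_ci", "acute_without_ci", "annual_mrs02",
             "annual_mrs35", "nh_annual")
  for (f in money)
    if (!is.numeric(cs[[f]]) || cs[[f]] < 0)
      fail("costs$%s: must be a non-negative dollar amount", f)
  for (f in c("nh_firstyear_factor", "y2to5_multiplier"))
    if (!is.numeric(cs[[f]]) || cs[[f]] <= 0)
      fail("costs$%s: must be a positive factor", f)
  if (cs$discount_rate < 0) fail("costs$discount_rate: must be >= 0")

  nh <- config$nursing_home
  for (f in c("retention_3mo_to_1y", "retention_1y_to_2y",
              "retention_1y_to_5y", "annual_rate_post5y")) {
    v <- nh[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      fail("nursing_home$%s: must be a fraction in [0, 1]", f)
  }
  if (nh$retention_1y_to_5y > nh$retention_1y_to_2y)
    fail("nursing_home: retention_1y_to_5y must not exceed retention_1y_to_2y")
  if (!nh$post5y_mode %in% c("share_of_alive", "retain_all", "retain_13pct"))
    fail("nursing_home$post5y_mode: unknown mode '%s'", nh$post5y_mode)
  for (f in c("mrs02", "mrs35")) {
    v <- nh$utilization_3mo[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      fail("nursing_home$utilization_3mo$%s: must be a fraction in [0, 1]", f)
  }

  th <- config$wtp$thresholds
  if (any(th <= 0) || any(diff(th) <= 0))
    fail("wtp$thresholds: must be positive and strictly increasing")

  co <- config$cohort
  if (co$n_patients <= 0) fail("cohort$n_patients: must be > 0")
  if (co$p_infarction < 0 || co$p_infarction > 1)
    fail("cohort$p_infarction: must be a fraction in [0, 1]")

  for (s in c("ci", "no_ci")) {
    sch <- config$schedule[[s]]
    for (d in c("dist_3mo", "dist_1y", "dist_2y", "dist_3y", "dist_5y"))
      validate_state_distribution(sch[[d]],
                                  what = sprintf("schedule$%s$%s", s, d))
    q <- sch$mortality_post5y
    if (any(q < 0) || any(q > 1))
      fail("schedule$%s$mortality_post5y: must be a probability", s)
    if (sch$nh_3mo < 0 || sch$nh_3mo > 1)
      fail("schedule$%s$nh_3mo: must be a fraction in [0, 1]", s)
  }

  a <- config$anchors
  lhs <- a$ci$cost_5y + a$no_ci$cost_5y + a$ci$cost_5to30 + a$no_ci$cost_5to30
  if (abs(lhs - a$printed_total_30y) > identity_tol)
    fail(paste0("anchors: 30-year identity violated: 5y totals + 5-to-30 ",
                "increments = %.2f but printed 30-year total is %.2f"),
         lhs, a$printed_total_30y)

  invisible(config)
}

#' Load a model configuration from a YAML file
#'
#' Reads a (possibly partial) YAML key-value document, overlays it on the
#' package defaults, and validates the result. An empty file yields the
#' default configuration. Keys absent from the file keep their defaults;
#' unknown keys raise an error so typos cannot silently be ignored.
#'
#' @param path path to a YAML configuration file.
#' @return A validated config list.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("costs:\n  nh_annual: 120000", f)
#' cfg <- load_config(f)
#' cfg$costs$nh_annual
load_config <- function(path) {
  if (!file.exists(path)) fail("config file not found: %s", path)
  user <- tryCatch(yaml::read_yaml(path), error = function(e)
    fail("config parse failure in %s: %s", path, conditionMessage(e)))
  if (is.null(user)) user <- list()
  if (!is.list(user)) fail("config file %s: top level must be a mapping", path)
  cfg <- merge_config(default_config(), user, path = "")
  validate_config(cfg)
  cfg
}

# Recursive overlay of user values on defaults; errors on unknown keys.
merge_config <- function(default, user, path = "") {
  if (!is.list(default) || !is.list(user) || is.null(names(default)))
    return(coerce_like(default, user, path))
  extra <- setdiff(names(user), names(default))
  if (length(extra))
    fail("config: unknown key%s %s", if (length(extra) > 1) "s" else "",
         paste0(sub("^\\$", "", paste0(path, "$", extra)), collapse = ", "))
  for (k in names(user))
    default[[k]] <- merge_config(default[[k]], user[[k]],
                                 paste0(path, "$", k))
  default
}

coerce_like <- function(default, user, path) {
  if (is.numeric(default) && !is.null(names(default))) {
    # named numeric vectors (state distributions) may arrive as YAML maps,
    # or as plain sequences in the default field order
    if (is.list(user)) user <- unlist(user)
    storage.mode(user) <- "double"
    if (is.null(names(user)) || !any(nzchar(names(user)))) {
      if (length(user) != length(default))
        fail("config%s: expected %d values (%s)", path, length(default),
             paste(names(default), collapse = "/"))
      names(user) <- names(default)
    }
    if (!all(names(default) %in% names(user)))
      fail("config%s: expected fields %s", path,
           paste(names(default), collapse = "/"))
    return(user[names(default)])
  }
  if (is.numeric(default) && is.list(user)) return(unlist(user))
  user
}

#' Write a model configuration to a YAML file
#'
#' Serializes a config so that `load_config()` round-trips it identically.
#'
#' @param config a config list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Adjust a dollar amount by an inflation/conversion factor
#'
#' Plain multiplicative CPI-style adjustment: `amount * factor`. The factor is
#' supplied by the caller (e.g. the ratio of a cost printed in 2025 dollars to
#' the same cost in 2023 dollars); the package performs no index lookups.
#'
#' @param amount numeric dollar amount(s); may be negative.
#' @param factor positive scalar ratio.
#' @return `amount * factor`.
#' @export
#' @examples
#' inflation_adjust(100, 2)         # 200
#' inflation_adjust(15332.03, 16280.15 / 15332.03)
inflation_adjust <- function(amount, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0)
    fail("inflation_adjust: factor must be a positive number")
  amount * factor
}

#' Path of the shipped default configuration file
#'
#' The package ships its complete default parameter set as a commented YAML
#' file (each key annotated with its provenance); this returns its path.
#'
#' @return File path of `default-config.yaml` in the installed package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default-config.yaml", package = "sahcue",
              mustWork = TRUE)
}
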