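#' Drug-regimen costing
#'
#' Acquisition costs of existing and candidate regimens from unit costs and
#' fixed dosing schedules: per dosing unit, per day, and for the full course.
#' Albumin dosing is bag-based: a prescribed dose of `dose_g_per_kg * weight`
#' grams is dispensed in whole 12.5 g bags (rounded up), so the "unit" is one
#' bag and one day holds one full dose. Combination regimens are
#' component-wise sums of the constituent columns; the summed per-unit figure
#' mixes different units (tablet + bag) and is retained for table fidelity as
#' a display-only quantity.
#'
#' @name interventions
NULL

#' Define a fixed-schedule dosing regimen
#'
#' @param name short identifier.
#' @param unit_cost USD per dosing unit.
#' @param units_per_day dosing units taken per day.
#' @param duration_days length of the course in days.
#' @param label optional human-readable description.
#' @return A `dosing_regimen` list.
#' @export
#' @examples
#' dosing_regimen("cilostazol_200", 0.13, 2, 14)
dosing_regimen <- function(name, unit_cost, units_per_day, duration_days,
                           label = name) {
  for (v in c(unit_cost, units_per_day, duration_days))
    if (!is.numeric(v) || v < 0) fail("dosing_regimen: fields must be >= 0")
  structure(list(name = name, label = label, unit_cost = unit_cost,
                 units_per_day = units_per_day,
                 duration_days = duration_days),
            class = "dosing_regimen")
}

#' Bags dispensed per albumin dose
#'
#' Whole 25% albumin bags needed to cover `dose_g_per_kg * weight_kg` grams:
#' `ceiling(required_g / bag_g)`.
#'
#' @param dose_g_per_kg prescribed dose, grams of albumin per kg body weight.
#' @param weight_kg patient weight.
#' @param bag_g grams of albumin per bag (12.5 for 25% albumin 50 mL).
#' @return Integer bag count.
#' @export
#' @examples
#' albumin_bags(1.25, 80, 12.5)  # 8
albumin_bags <- function(dose_g_per_kg, weight_kg, bag_g = 12.5) {
  if (bag_g <= 0) fail("albumin_bags: bag size must be positive")
  if (dose_g_per_kg < 0 || weight_kg < 0)
    fail("albumin_bags: dose and weight must be >= 0")
  as.integer(ceiling(dose_g_per_kg * weight_kg / bag_g))
}

#' Albumin course as a dosing regimen
#'
#' Translates bag-dispensing arithmetic into the regimen frame: the dosing
#' unit is one bag, one day carries one full dose (all bags), and the course
#' lasts `n_doses` days.
#'
#' @param bag_cost USD per bag.
#' @param dose_g_per_kg,weight_kg,bag_g dose arithmetic, see [albumin_bags()].
#' @param n_doses number of once-daily doses in the course.
#' @param name,label identifiers.
#' @return A `dosing_regimen`.
#' @export
albumin_regimen <- function(bag_cost = 55.87, dose_g_per_kg = 1.25,
                            weight_kg = 80, bag_g = 12.5, n_doses = 1,
                            name = "albumin", label = name) {
  bags <- albumin_bags(dose_g_per_kg, weight_kg, bag_g)
  dosing_regimen(name, unit_cost = bag_cost, units_per_day = bags,
                 duration_days = n_doses, label = label)
}

#' Cost of a dosing regimen
#'
#' @param r a `dosing_regimen`.
#' @return Named numeric: `per_unit`, `per_day`
#'   (`unit_cost * units_per_day`), `total` (`per_day * duration_days`).
#' @export
#' @examples
#' regimen_cost(dosing_regimen("cilostazol_200", 0.13, 2, 14))
regimen_cost <- function(r) {
  if (!inherits(r, "dosing_regimen")) fail("regimen_cost: not a dosing_regimen")
  per_day <- r$unit_cost * r$units_per_day
  c(per_unit = r$unit_cost, per_day = per_day,
    total = per_day * r$duration_days)
}

#' Cost of a combination regimen
#'
#' Component-wise sums of the constituents' per-unit, per-day and course
#' costs. Order-invariant and additive; an empty combination costs nothing.
#'
#' @param regimens list of `dosing_regimen` objects.
#' @return Named numeric: `per_unit` (display-only; units differ across
#'   constituents), `per_day`, `total`.
#' @export
combo_cost <- function(regimens) {
  out <- c(per_unit = 0, per_day = 0, total = 0)
  for (r in regimens) out <- out + regimen_cost(r)
  out
}

# Build the regimen objects from the config catalogue.
catalog_regimens <- function(config) {
  specs <- config$drugs$regimens
  out <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    if (isTRUE(sp$albumin))
      albumin_regimen(bag_cost = sp$bag_cost, dose_g_per_kg = sp$dose_g_per_kg,
                      weight_kg = sp$weight_kg, bag_g = sp$bag_g,
                      n_doses = sp$n_doses, name = nm, label = sp$label)
    else
      dosing_regimen(nm, sp$unit_cost, sp$units_per_day, sp$duration_days,
                     label = sp$label)
  })
  names(out) <- names(specs)
  out
}

#' Therapeutic-agent cost table
#'
#' Reproduces the regimen cost table from unit costs and dosing rules: one
#' row per single regimen and per configured combination, plus the
#' clazosentan row (stored as its published 2023 and 2025 USD figures, the
#' 2025 value being the CPI adjustment of the 2023 one; no FX modelling).
#'
#' @param config validated config list.
#' @return data.frame: `regimen`, `label`, `per_unit`, `per_day`, `total`.
#' @export
#' @examples
#' drug_cost_table(default_config())
drug_cost_table <- function(config) {
  regs <- catalog_regimens(config)
  rows <- lapply(names(regs), function(nm) {
    cc <- regimen_cost(regs[[nm]])
    data.frame(regimen = nm, label = regs[[nm]]$label,
               per_unit = cc[["per_unit"]], per_day = cc[["per_day"]],
               total = cc[["total"]])
  })
  combos <- config$drugs$combos
  rows <- c(rows, lapply(names(combos), function(nm) {
    parts <- regs[combos[[nm]]]
    if (anyNA(names(parts))) fail("combo '%s' references unknown regimens", nm)
    cc <- combo_cost(parts)
    data.frame(regimen = nm,
               label = paste(vapply(parts, `[[`, "", "label"),
                             collapse = " + "),
               per_unit = cc[["per_unit"]], per_day = cc[["per_day"]],
               total = cc[["total"]])
  }))
  cz <- config$drugs$clazosentan
  if (!is.null(cz)) {
    f <- cz$usd_2025 / cz$usd_2023
    rows <- c(rows, list(data.frame(
      regimen = "clazosentan", label = cz$label, per_unit = NA_real_,
      per_day = NA_real_,
      total = inflation_adjust(cz$usd_2023, f))))
  }
  out <- do.call(rbind, rows)
  out[c("per_unit", "per_day", "total")] <-
    lapply(out[c("per_unit", "per_day", "total")], round_half_up, digits = 2)
  out
}
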