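#' Incremental cost-utility analytics
#'
#' Comparisons between the base case (35% infarction) and reduced-infarction
#' scenarios: cost saved, QALYs gained, the incremental cost-utility ratio
#' ICER = (n * cost_per_patient - cost_saved) / qaly_gain, and classification
#' against willingness-to-pay thresholds with a strict "<" convention. An
#' intervention that both saves money (negative ICER numerator) and gains
#' QALYs is dominant (cost-saving); the raw negative ICER is retained in
#' tables.
#'
#' @name cua
NULL

WTP_CLASSES <- c("dominant", "ce_under_50k", "ce_under_100k",
                 "ce_under_150k", "not_ce")

#' Cost saved by an intervention scenario
#'
#' @param base,alt one-row scenario data.frames from [scenario_totals()] at
#'   the same horizon (base = higher infarction proportion).
#' @return USD saved, `base$total_cost - alt$total_cost`; negative when the
#'   reduced-infarction scenario is the more expensive one (as at 30 years,
#'   where survivors accumulate costs for longer).
#' @export
cost_saved <- function(base, alt) {
  check_comparable(base, alt)
  base$total_cost - alt$total_cost
}

#' QALYs gained by an intervention scenario
#'
#' @inheritParams cost_saved
#' @return QALY difference `alt$total_qaly - base$total_qaly`.
#' @export
qaly_gained <- function(base, alt) {
  check_comparable(base, alt)
  alt$total_qaly - base$total_qaly
}

check_comparable <- function(base, alt) {
  if (!isTRUE(all.equal(base$horizon, alt$horizon)))
    fail("scenarios have different horizons (%s vs %s)",
         base$horizon, alt$horizon)
}

#' Incremental cost-utility ratio
#'
#' `(n * cost_per_patient - cost_saved) / qaly_gain`: the net cohort cost of
#' the intervention per QALY gained.
#'
#' @param cost_per_patient intervention cost, USD per patient.
#' @param n cohort size.
#' @param cost_saved USD saved by the infarction reduction (may be negative).
#' @param qaly_gain QALYs gained; must be non-zero.
#' @return USD per QALY (may be negative = cost-saving).
#' @export
#' @examples
#' icer(10000, 100, 856706, 1.8)
icer <- function(cost_per_patient, n, cost_saved, qaly_gain) {
  if (cost_per_patient < 0) fail("icer: cost_per_patient must be >= 0")
  if (!is.finite(qaly_gain) || qaly_gain == 0)
    fail("icer: undefined for a zero QALY gain")
  (n * cost_per_patient - cost_saved) / qaly_gain
}

#' Willingness-to-pay classification of an ICER
#'
#' With a positive QALY gain: a negative ICER is dominant (cost-saving);
#' otherwise the class is the smallest threshold `T` with `icer_value < T`
#' (strict comparison), or `not_ce` above all thresholds. A non-positive
#' QALY gain is never cost-effective.
#'
#' @param icer_value USD/QALY.
#' @param qaly_gain QALYs gained by the intervention.
#' @param thresholds increasing USD/QALY bounds (default 50k/100k/150k).
#' @return One of `"dominant"`, `"ce_under_50k"`, `"ce_under_100k"`,
#'   `"ce_under_150k"`, `"not_ce"` (with non-default thresholds,
#'   `"ce_under_<k>k"` labels are derived from the bounds).
#' @export
#' @examples
#' classify_wtp(72125, 3.3)
#' classify_wtp(-3934, 2.6)
classify_wtp <- function(icer_value, qaly_gain,
                         thresholds = c(50000, 100000, 150000)) {
  if (any(thresholds <= 0) || any(diff(thresholds) <= 0))
    fail("thresholds must be positive and strictly increasing")
  if (!is.finite(qaly_gain) || qaly_gain <= 0) return("not_ce")
  if (icer_value < 0) return("dominant")
  labels <- sprintf("ce_under_%gk", thresholds / 1000)
  hit <- which(icer_value < thresholds)
  if (!length(hit)) "not_ce" else labels[hit[1L]]
}

#' Full ICER grid across horizons, reductions and intervention costs
#'
#' Recomputes, for every (horizon, reduction) pair, the cost saved and QALYs
#' gained between the base case and the reduced-infarction scenario, then the
#' ICER and WTP class for each intervention cost. In anchor mode QALY gains
#' are rounded to one decimal (the precision of the published aggregate
#' estimates) before division; `qaly_precision = "full"` keeps full
#' precision.
#'
#' @param config validated config list.
#' @param horizons evaluation horizons (default 1, 5, 30).
#' @param reductions_pct percentage-point reductions in infarction incidence.
#' @param costs_per_patient intervention costs, USD per patient.
#' @param mode `"anchor"` or `"mechanistic"` scenario engine.
#' @param qaly_precision `"printed"` (one decimal; anchor-mode default) or
#'   `"full"`.
#' @return Long data.frame: `horizon`, `reduction_pct`, `p_alt`,
#'   `cost_saved`, `qaly_gain`, `cost_per_patient`, `icer`, `wtp_class`.
#' @export
#' @examples
#' g <- icer_grid(default_config(), horizons = 5)
#' subset(g, reduction_pct == 15)
icer_grid <- function(config, horizons = c(1, 5, 30),
                      reductions_pct = config$interventions$reductions_pct,
                      costs_per_patient = config$interventions$costs_per_patient,
                      mode = c("anchor", "mechanistic"),
                      qaly_precision = NULL) {
  mode <- match.arg(mode)
  qaly_precision <- qaly_precision %||%
    (if (mode == "anchor") "printed" else "full")
  n <- config$cohort$n_patients
  p0 <- config$cohort$p_infarction
  rows <- list()
  for (h in horizons) {
    base <- scenario_totals(config, p = p0, horizon = h, mode = mode)
    for (r in reductions_pct) {
      if (r < 0 || r / 100 > p0)
        fail("reduction of %s points is outside [0, base rate]", r)
      alt <- scenario_totals(config, p = p0 - r / 100, horizon = h,
                             mode = mode)
      cs <- cost_saved(base, alt)
      qg <- qaly_gained(base, alt)
      if (qaly_precision == "printed") qg <- round_half_up(qg, 1)
      for (cpp in costs_per_patient) {
        ic <- if (qg == 0) NA_real_ else icer(cpp, n, cs, qg)
        rows[[length(rows) + 1L]] <- data.frame(
          horizon = h, reduction_pct = r, p_alt = p0 - r / 100,
          cost_saved = cs, qaly_gain = qg, cost_per_patient = cpp,
          icer = ic,
          wtp_class = if (is.na(ic)) NA_character_
                      else classify_wtp(ic, qg, config$wtp$thresholds))
      }
    }
  }
  do.call(rbind, rows)
}
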