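# sahcue default model configuration
# ----------------------------------
# Single source of truth for every model constant. Each key carries a
# provenance note: [published] = printed in the source cost-utility analysis;
# [derived] = arithmetic consequence of published figures;
# [calibrated] = back-solved so the mechanistic cohort model reproduces the
# published aggregate anchors (NOT a literature value);
# [package] = engine choice documented in the methods vignette.
# Any key omitted from a user config falls back to the value below.

cohort:
  n_patients: 100          # [published] hypothetical aSAH cohort size
  p_infarction: 0.35       # [published] base-case cerebral infarction rate
  scenario_proportions: [0.35, 0.30, 0.25, 0.20]  # [published] scenario grid

utilities:                 # [published] utility weight per year in state
  independent: 0.74        # functionally independent, mRS 0-2
  dependent: 0.38          # functionally dependent, mRS 3-5
  dead: 0.0

costs:
  acute_with_ci: 122200.96    # [published] USD/patient, acute stay, with infarction
  acute_without_ci: 89997.00  # [published] USD/patient, acute stay, without infarction
  annual_mrs02: 14293.80      # [published] USD/year post-hospital care, mRS 0-2
  annual_mrs35: 15633.30      # [published] USD/year post-hospital care, mRS 3-5
  nh_annual: 114665.00        # [published] USD/year nursing home residence
  nh_firstyear_factor: 0.85   # [published] first-year discharge adjustment
  y2to5_multiplier: 1.33      # [published] 3 evaluated years -> 4-year block
  discount_rate: 0.0          # [package] discounting hook; source model uses none

nursing_home:
  retention_3mo_to_1y: 0.70   # [published] residents at 3 months still in at 1 year
  retention_1y_to_2y: 0.61    # [published] residents at 1 year still in at 2 years
  retention_1y_to_5y: 0.36    # [published] residents at 1 year still in at 5 years
  annual_rate_post5y: 0.13    # [published] annual nursing-home rate after year 5
  post5y_mode: share_of_alive # [package] see vignette; also retain_all, retain_13pct
  utilization_3mo:            # [package] per-band 3-month utilization split
    mrs02: 0.05
    mrs35: 0.75

wtp:
  thresholds: [50000.0, 100000.0, 150000.0]  # [published] USD/QALY, strict "<"

anchors:
  # [published] stratum aggregate cost/QALY anchors. 1y and 5y costs are
  # cumulative from admission; cost_5to30 is the years-5-to-30 increment
  # (the only reading consistent with the printed 30-year cohort total).
  ci:
    n_strat: 35
    cost_1y: 5982964
    qaly_1y: 14.0
    cost_5y: 9529902.30
    qaly_5y: 13.5
    cost_5to30: 10112038
    qaly_30y: 3.08
  no_ci:
    n_strat: 65
    cost_1y: 7794976
    qaly_1y: 42.9
    cost_5y: 12303601.90
    qaly_5y: 42.6
    cost_5to30: 28969455
    qaly_30y: 15.2
  printed_total_30y: 60914997   # [published] 30-year cohort total
  table2:
    # [published] 5- and 30-year scenario cells for the reduced proportions;
    # not affine in the infarction proportion, stored verbatim.
    p030: {cost_5y: 21371192,    qaly_5y: 56.8, cost_30y: 60546080, qaly_30y: 18.8}
    p025: {cost_5y: 20976797,    qaly_5y: 57.9, cost_30y: 61075366, qaly_30y: 19.5}
    p020: {cost_5y: 20571518.30, qaly_5y: 59.4, cost_30y: 61177403, qaly_30y: 20.2}

schedule:
  # [calibrated] three-state schedule: frozen output of calibrate_schedule().
  # NOT literature values; see the methods vignette for the solve and its
  # residuals/artifacts.
  calibrated: true
  ci:
    dist_3mo: {independent: 0.5611346990, dependent: 0.4213335780, dead: 0.0175317230}
    dist_1y:  {independent: 0.0773269763, dependent: 0.9020474671, dead: 0.0206255566}
    dist_2y:  {independent: 0.1155645681, dependent: 0.6621427167, dead: 0.2222927152}
    dist_3y:  {independent: 0.1676479880, dependent: 0.6005426068, dead: 0.2318094052}
    dist_5y:  {independent: 0.2710801593, dependent: 0.4871446522, dead: 0.2417751885}
    mortality_post5y: 0.0573973033   # [calibrated] annual, both alive states
    nh_3mo: 0.3440569184             # [calibrated] 3-month NH occupancy
  no_ci:
    dist_3mo: {independent: 0.8466709413, dependent: 0.1533290587, dead: 0.0}
    dist_1y:  {independent: 0.7777777778, dependent: 0.2222222222, dead: 0.0}
    dist_2y:  {independent: 0.7668407509, dependent: 0.2089550442, dead: 0.0242042049}
    dist_3y:  {independent: 0.7747292166, dependent: 0.2010665784, dead: 0.0242042050}
    dist_5y:  {independent: 0.7905061481, dependent: 0.1852896468, dead: 0.0242042051}
    mortality_post5y: 0.0403842672
    nh_3mo: 0.1573303411

interventions:
  costs_per_patient: [5000.0, 10000.0, 15000.0, 20000.0]  # [published] USD/patient grid
  reductions_pct: [5.0, 10.0, 15.0]   # [published] infarction reduction, pct points

drugs:
  # [published] NADAC/AWP 2025 unit costs and fixed dosing schedules
  regimens:
    cilostazol_200:
      label: Cilostazol 100 mg tablet (200 mg/d x 14 days)
      unit_cost: 0.13
      units_per_day: 2
      duration_days: 14
    cilostazol_300:
      label: Cilostazol 100 mg tablet (300 mg/d x 14 days)
      unit_cost: 0.13
      units_per_day: 3
      duration_days: 14
    albumin_x1:
      label: IV 25% humanized albumin (1.25 g/kg dose x 1 dose)
      albumin: true
      bag_cost: 55.87       # [published] AWP per 12.5 g bag
      dose_g_per_kg: 1.25
      weight_kg: 80
      bag_g: 12.5
      n_doses: 1
    albumin_x7:
      label: IV 25% humanized albumin (1.25 g/kg dose x 7 doses)
      albumin: true
      bag_cost: 55.87
      dose_g_per_kg: 1.25
      weight_kg: 80
      bag_g: 12.5
      n_doses: 7
    nimodipine:
      label: Nimodipine 30 mg capsules (60 mg q4h) x 21 days
      unit_cost: 1.09
      units_per_day: 12
      duration_days: 21
  combos:
    cilostazol200_albumin1: [cilostazol_200, albumin_x1]
    cilostazol200_albumin1_nimodipine: [cilostazol_200, albumin_x1, nimodipine]
    cilostazol300_albumin7: [cilostazol_300, albumin_x7]
  clazosentan:
    label: IV Clazosentan
    jpy: 2215691            # [published] Japanese market price
    usd_2023: 15332.03      # [published] USD conversion, 2023 dollars
    usd_2025: 16280.15      # [published] CPI-adjusted 2025 dollars
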