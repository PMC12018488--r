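# Default interpretable-covariate recoding for the Look-AHEAD-like roster.
# Intervals are half-open [lo, hi) on the stated lower bounds: printed ranges
# like "6.4-6.9" reflect one-decimal rounding, so HbA1c 6.95 still falls in
# "6.4–6.9" and exactly 7.0 falls in "7.0–7.9".
#
# Notes on transcription oddities, preserved deliberately:
#   * fasting_glucose groups (< 54, 54–69.9, >= 70) look clinically unusual
#     (hypoglycemic cutpoints for a diabetes population) but are transcribed
#     verbatim from the source coding table.
#   * beck_depression prints "<= 10, 10–19, ..."; the overlap at 10 is
#     resolved by putting 10 in the first group (cutpoint at 11; the score is
#     integer-valued).
#   * alcohol is dichotomized at any positive weekly consumption.
unlisted_policy: keep
rules:
  age:
    action: categorize
    cutpoints: [60]
    labels: ["< 60", "≥ 60"]
  bmi:
    action: categorize
    cutpoints: [18.5, 25, 30, 35, 40]
    labels: ["< 18.5", "18.5–24.9", "25–29.9", "30–34.9", "35–39.9", "≥ 40"]
  alcohol_oz_wk:
    action: categorize
    cutpoints: [0.01]
    labels: ["Do Not Drink Alcohol", "Drink Alcohol"]
  fasting_glucose:
    action: categorize
    cutpoints: [54, 70]
    labels: ["< 54", "54–69.9", "≥ 70"]
  hba1c:
    action: categorize
    cutpoints: [5.7, 6.4, 7.0, 8.0, 9.0, 10]
    labels: ["< 5.7", "5.7–6.3", "6.4–6.9", "7.0–7.9", "8.0–8.9", "9.0–9.9", "≥ 10"]
  hdl:
    action: categorize
    cutpoints: [40, 60]
    labels: ["< 40", "40–59.9", "≥ 60"]
  ldl:
    action: categorize
    cutpoints: [100, 130, 160, 190]
    labels: ["< 100", "100–129.9", "130–159.9", "160–189.9", "≥ 190"]
  triglycerides:
    action: categorize
    cutpoints: [150, 200, 500]
    labels: ["< 150", "150–199.9", "200–499.9", "≥ 500"]
  urine_albumin:
    action: remove
  urine_creatinine:
    action: remove
  urine_acr:
    action: categorize
    cutpoints: [30, 300]
    labels: ["< 30", "30–299", "≥ 300"]
  sbp:
    action: categorize
    cutpoints: [120, 130, 140, 160, 180]
    labels: ["< 120", "120–129.9", "130–139.9", "140–159.9", "160–179.9", "≥ 180"]
  sf36_general_health:
    action: categorize
    cutpoints: [50]
    labels: ["< 50", "≥ 50"]
  sf36_mental_health:
    action: categorize
    cutpoints: [50]
    labels: ["< 50", "≥ 50"]
  sf36_bodily_pain:
    action: categorize
    cutpoints: [50]
    labels: ["< 50", "≥ 50"]
  sf36_physical_functioning:
    action: categorize
    cutpoints: [50]
    labels: ["< 50", "≥ 50"]
  sf36_role_emotional:
    action: categorize
    cutpoints: [50]
    labels: ["< 50", "≥ 50"]
  sf36_role_physical:
    action: categorize
    cutpoints: [50]
    labels: ["< 50", "≥ 50"]
  sf36_social_functioning:
    action: categorize
    cutpoints: [50]
    labels: ["< 50", "≥ 50"]
  sf36_vitality:
    action: categorize
    cutpoints: [50]
    labels: ["< 50", "≥ 50"]
  sf36_transition:
    action: remove
  sf36_mcs:
    action: remove
  sf36_pcs:
    action: remove
  beck_depression:
    action: categorize
    cutpoints: [11, 20, 30]
    labels: ["≤ 10", "10–19", "20–29", "≥ 30"]
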