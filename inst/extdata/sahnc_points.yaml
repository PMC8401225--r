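# Points-band tables for the SA health-and-nutrition-claims scored model,
# following the FSANZ NPSC band structure referenced by draft R429.
# Regulatory revisions are config edits, not code changes.
#
# Baseline points: n points when the value strictly exceeds n * step,
# capped. cap_category3 applies to the processed-cheese/fats scoring
# category where the ladder extends further.
baseline:
  energy_kJ:      {step: 335, cap: 10}
  sat_fat_g:      {step: 1,   cap: 10, cap_category3: 30}
  total_sugar_g:  {step: 4.5, cap: 10}
  sodium_mg:      {step: 90,  cap: 10, cap_category3: 30}
modifying:
  protein_g:      {step: 1.6, cap: 5}
  fiber_g:        {step: 0.9, cap: 5}
  fvnl_percent:
    ladder:
      - {above: 40, points: 1}
      - {above: 60, points: 2}
      - {above: 80, points: 5}
# Protein points are barred for products with a high baseline score unless
# the FVNL points reach the minimum.
protein_cap:
  baseline_at_least: 13
  min_fvnl_points: 5
# Final-score thresholds for compliance (strictly less than).
compliance:
  beverage: 1
  cheese_or_fat: 28
  other: 4
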