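# Chile Warning Octagon, final-phase (2019) limits per 100 g / 100 mL.
# Sugar/saturated-fat/sodium limits as adopted for the proposed SA model.
# Energy limits are externally sourced from the Chilean regulation
# (275 kcal/100 g solids, 70 kcal/100 mL liquids, converted at 4.184 kJ/kcal)
# and are not restated in the SA analyses.
name: cwo2019
includes_energy: true
includes_nss: false
comparison: gt
solids:
  energy_kJ: 1150.6
  total_sugar_g: 10
  sat_fat_g: 4
  sodium_mg: 400
liquids:
  energy_kJ: 292.88
  total_sugar_g: 5
  sat_fat_g: 3
  sodium_mg: 100
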