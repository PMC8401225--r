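# Proposed SA restrictive NPM: across-the-board cut-points adapted from the
# Chilean approach. Energy is not evaluated; any non-sugar-sweetener content
# flags. Qualifying criteria (free-sugar source, added sodium, added
# saturated fat) gate the nutrient limits and are handled by the classifier.
name: sa_proposed
includes_energy: false
includes_nss: true
comparison: gt
solids:
  sodium_mg: 400
  total_sugar_g: 10
  sat_fat_g: 4
liquids:
  sodium_mg: 100
  total_sugar_g: 5
  sat_fat_g: 3
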