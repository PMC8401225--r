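# foodnpm

Nutrient profiling models (NPMs) for packaged-food supply analysis, built
for public-health nutrition researchers and policy analysts working on
restrictive food policies (front-of-package warning labels, marketing and
school-food restrictions) in South Africa and comparable settings.

An NPM classifies each packaged product from its per-100 g (solids) or
per-100 mL (liquids) nutrition declaration. `foodnpm` implements three:

* **Chile Warning Octagon 2019** — threshold model over energy, total
  sugar, saturated fat and sodium. A product is non-compliant iff any
  value strictly exceeds its form-specific limit; the sugar limit applies
  only to products containing added sugar, salt or saturated fat.
* **SA HNC scored model** (FSANZ-derived, draft R429), final and baseline
  variants — baseline points from band tables (energy 1 pt/335 kJ,
  saturated fat 1 pt/g, total sugar 1 pt/4.5 g, sodium 1 pt/90 mg; caps 10,
  extended to 30 for cheese/fats), minus modifying points for protein,
  fibre and fruit/vegetable/nut/legume (FVNL) content in the final variant.
  Compliant iff score < 1 (beverages), < 28 (cheese/fats), < 4 (other).
* **Proposed SA restrictive NPM** — across-the-board cut-points adapted
  from Chile (solids: 400 mg sodium, 10 g total sugar, 4 g saturated fat
  per 100 g; liquids: 100/5/3 per 100 mL), gated by qualifying criteria
  (free-sugar source, added sodium, added saturated fat) and flagging any
  non-sugar-sweetener (NSS) content. Missing information defaults to
  excessive.

Around the models: free-sugar estimation rules, NSS detection from
ingredient text with a versioned sweetener term list, a banded FVNL
estimator, WHO-aligned per-energy sugar limits (1 g total sugar per 168 kJ,
1 g free sugar per 336 kJ on an 8400 kJ/day reference), whole-food
cut-point context checks against a food-composition-table extract,
category-level supply summaries, and a seeded synthetic supply generator
parameterised by the published 2018 SA category profile.

## Worked example

```r
library(foodnpm)

products <- tibble::tibble(
  product_id = c("cereal-1", "soda-1", "juice-1"),
  category = c("breakfast cereals", "sodas", "100% fruit juice"),
  form = c("solid", "liquid", "liquid"),
  energy_kJ = c(1600, 180, 190),
  total_sugar_g = c(22, 9, 10.4),
  total_fat_g = c(9, 0, 0),
  sat_fat_g = c(3, 0, 0),
  sodium_mg = c(350, 20, 10),
  ingredients_text = c("wheat, sugar, salt", "water, sugar, flavouring",
                       "apple juice"),
  contains_free_sugar_source = c(TRUE, TRUE, FALSE),
  contains_added_sodium = c(TRUE, FALSE, FALSE),
  contains_added_sat_fat = c(TRUE, FALSE, FALSE),
  contains_nss = FALSE
)

res <- classify_sa_proposed(products)
res[, c("product_id", "flag_sugar", "flag_sodium", "flag_sat_fat",
        "flag_nss", "compliant")]
#> # A tibble: 3 × 6
#>   product_id flag_sugar flag_sodium flag_sat_fat flag_nss compliant
#>   <chr>      <lgl>      <lgl>       <lgl>        <lgl>    <lgl>
#> 1 cereal-1   TRUE       FALSE       FALSE        FALSE    FALSE
#> 2 soda-1     TRUE       FALSE       FALSE        FALSE    FALSE
#> 3 juice-1    FALSE      FALSE       FALSE        FALSE    TRUE
```

The cereal (22 g sugar > 10 g solid limit, free-sugar source present) and
the soda (9 g > 5 g liquid limit) flag for sugar; the juice exceeds the
numeric sugar limit too (10.4 g > 5 g) but carries no free-sugar *source*
per its qualifying criteria, so the limit does not apply and it is
compliant — the behaviour that makes the qualifying criteria, not the
cut-point, the policy lever for juices.

Guideline arithmetic at a stratum's mean energy density:

```r
who_aligned_limit(1072.8, "total")    # 6.4  g/100 g aligned with WHO guidance
pct_energy_from_sugar(13.4, 1072.8)   # 21.2 % of energy from total sugar
```

A seeded synthetic supply with the published category structure:

```r
supply <- generate_supply(default_generator_config(seed = 1, n_scale = 0.1))
compare_models(supply)   # compliance per category under all four model variants
```

A thin command-line wrapper ships at `inst/cli/foodnpm.R` with subcommands
`profile`, `simulate`, `summarize` and `cutpoints`.

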