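---
title: "Nutrient profiling models for packaged-food supply analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient profiling models for packaged-food supply analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodnpm)
```

## The problem

Restrictive food policies — front-of-package warning labels, marketing
restrictions, school-food rules — need a nutrient profiling model (NPM): a
formal procedure that classifies each packaged product as compliant or not
from its nutrition information panel (NIP). `foodnpm` implements the three
models relevant to the South African policy debate and the estimation
machinery they need, over a common tabular product representation
(one row per product; nutrient declarations per 100 g for solids, per
100 mL for liquids; missing declarations are `NA`, never 0).

The three models:

* **Chile Warning Octagon 2019** (`classify_cwo()`): an across-the-board
  threshold model. A product is non-compliant when any of energy, total
  sugar, saturated fat or sodium **strictly exceeds** its form-specific
  limit. The sugar limit is applied only to products that contain added
  sugar, salt or saturated fat, so intrinsically sugary products (fresh
  fruit, 100% juice) are not caught by it.
* **SA HNC scored model** (`score_sahnc()`): the FSANZ-derived scoring
  model in South Africa's draft claims regulation. Baseline points
  accumulate from band tables for energy (1 pt / 335 kJ), saturated fat
  (1 pt / g), total sugar (1 pt / 4.5 g) and sodium (1 pt / 90 mg), each
  capped at 10 (30 for saturated fat and sodium in the processed
  cheese/fats category). The *final* variant subtracts modifying points for
  protein (1 pt / 1.6 g, cap 5), fibre (1 pt / 0.9 g, cap 5) and FVNL
  content (1/2/5 pts above 40/60/80%); protein points are barred at a
  baseline of 13+ unless FVNL points reach 5. The *baseline* variant awards
  no modifying points. Compliance is a strict score threshold: < 1 for
  beverages, < 28 for processed cheese and fats, < 4 otherwise. Because
  modifying points are non-negative, the final-variant compliant set always
  contains the baseline-variant set — the leniency that "nutrients to
  encourage" introduce.
* **Proposed SA restrictive NPM** (`classify_sa_proposed()`): across-the-board
  cut-points adapted from the Chilean approach — solids 400 mg sodium / 10 g
  total sugar / 4 g saturated fat per 100 g, liquids 100 mg / 5 g / 3 g per
  100 mL — with qualifying criteria per nutrient (free-sugar source, added
  sodium, added saturated fat) and a flag for *any* non-sugar-sweetener
  (NSS) content. Energy is not evaluated: in the 2018 SA supply only 2.3%
  of CWO-regulated products exceeded the energy limit alone, so the other
  three nutrients capture nearly everything energy would.

## Boundary semantics and missing data

"Exceeds" is strictly greater-than everywhere: a solid with exactly 400 mg
sodium/100 g is compliant. This is centralised in the `npm_thresholds`
object (`comparison = "gt"`); a ≥ dialect is a one-line config change.
Band points likewise require strictly exceeding `n × step`.

Missing values are handled by explicit policy. `classify_cwo()` refuses to
guess: the caller chooses `missing = "excessive"` or `"permissive"`. The
proposed model bakes in the default-excessive stance: a missing value in a
*qualified* nutrient flags, and an unknown qualifying flag resolves to
qualified. Unknown NSS status (no ingredient list) also resolves to
flagged. These defaults are deliberately conservative toward flagging — a
restrictive policy should not reward absent information. When a product
carries both an as-consumed and an as-packaged declaration, the as-consumed
one is profiled (`prefer_basis()`).

## Estimation layers

**Free sugar** cannot be assayed apart from total sugar, so
`estimate_free_sugar()` fills undeclared values by category rule
(`all_free`, `none_free`, or a fixed fraction), returning a provenance tag.
The shipped defaults encode the two defensible anchors — sugar in sodas is
entirely free; intrinsic lactose and intact-plant sugar are not free — and
treat juice sugars as free per the WHO definition. Published survey tables
show a 100%-juice free-sugar mean well below its total-sugar mean; no
stated rule reproduces that split, so we document rather than emulate it.
Real mixed categories need survey-specific fractional rules.

**NSS detection** (`detect_nss()`) lower-cases, strips punctuation and
matches the term list with word-boundary guards ("polysaccharide" never
matches saccharin). The shipped list covers the standard intense sweeteners
and polyols with synonyms and E-numbers (E950–E969 and polyol codes); it is
versioned YAML so a study's exact search-term list can be dropped in.
Empty ingredient text yields *unknown*, not *false*. Detection is monotone
in the term list and invariant to case and ingredient order.

**FVNL scoring** (`estimate_fvnl_percent()`) emulates manual dietitian
scoring with a deterministic banded heuristic: negligible tokens (water,
salt, processing aids) are dropped; the rank of the first
fruit/vegetable/nut/legume ingredient sets the starting band
(0/25/50/75/100); concentrated forms (paste, powder, concentrate) and a low
FVNL share each demote one band. This reproduces the clear-cut cases
(a food whose first real ingredient is a whole legume scores the top band;
no FVNL tokens scores 0; ineligible categories such as fats and oils always
score 0) but it is an emulation of expert judgement, not a validated
replacement for it.

**Guideline arithmetic** (`who_aligned_limit()`,
`pct_energy_from_sugar()`): on a reference intake of 8400 kJ/day, the WHO
shares (10% of energy from total sugar, 5% from free sugar) translate to
1 g total sugar per 168 kJ and 1 g free per 336 kJ; the aligned limit for a
stratum with mean energy density E is E/168 (total) or E/336 (free) grams
per 100 g/mL. Percent-of-energy uses the 17 kJ/g label convention. Note the
one-constant tension: 168 kJ/g implies 16.8 kJ/g of sugar, but reported
%-energy figures follow 17 kJ/g; each constant is used exactly where the
corresponding reporting convention uses it (`sugar_constants()` documents
both).

## The synthetic supply generator

The 2018 SA survey dataset (6,747 products) is not redistributable, so
`generate_supply()` emulates its published *category-level* profile: the
15 sub-category sizes, nutrient means and NSS prevalences shipped in
`sa_category_summary()`. Nutrient amounts are drawn log-normally
(right-skewed, non-negative), parameterised to hit each configured mean at
a coefficient of variation of 0.6 — a modelling choice, since the published
summaries carry only means. Saturated and trans fat are beta-distributed
fractions of total fat and free sugar is a fixed category-level fraction of
total sugar, so every panel invariant holds by construction. NSS flags are
independent Bernoulli draws with the configured prevalence, and flagged
products get a real sweetener token synthesised into their ingredient text
so detection and declaration agree.

What the generator does *not* emulate: product-level correlations between
nutrients, within-category subpopulations (e.g. diet vs regular sodas), or
dispersion shapes beyond the single CV. Tests that pass on generated
supplies therefore demonstrate the *mechanics* of classification and
aggregation at realistic magnitudes — they do not reproduce the survey's
headline compliance percentages, which depend on the unreleased
product-level data and are out of scope here.

Hand-authored fixtures (`fixture_supply()`) complement the generator with
known-answer cases: products sitting exactly at, just under and just over
every proposed cut-point; an energy-only-flagged product; and a product
rescued by modifying points (compliant under the final scored variant,
non-compliant under baseline).

## Numerical choices

* Reported percentages round half-up (`round_half_up()`), matching
  label/table conventions; per-nutrient compliance shares print as whole
  percents, others to 1 decimal place.
* Strict-exceed comparisons use a relative epsilon guard so at-limit values
  never flag through floating-point noise.
* kcal convert at 4.184 kJ/kcal.
* FCT percentiles (`distribution_summary()`) are type-1 empirical
  quantiles — actual order statistics, no interpolation — so they agree
  with a sort-based recomputation exactly.
* Rollup rows in `summarize_categories()` are pooled means over products,
  never means of category means. The shipped published summary carries its
  source's rollup rows verbatim (its beverage rollup is not exactly the
  pooled mean of its category rows), and downstream arithmetic uses those
  printed rows as inputs.
* Generation, and every other stochastic path, requires an explicit seed;
  the generator restores the caller's RNG state on exit.

## Problem sizes

The test suite exercises supplies of roughly 300–1,000 generated products
per case, ten seeds for the nesting property, and a single n = 10⁴ draw for
generator parameter recovery (3-standard-error criterion); the whole suite
runs in well under a minute. `scripts/acceptance.R` re-runs the same
computations from the installed package and writes them as JSON.

## Known limitations

* The CWO energy limits ship from the Chilean regulation (275 kcal/100 g,
  70 kcal/100 mL) because the SA analyses restate only the other three
  nutrients; they are clearly marked externally sourced in the config.
* The FSANZ/R429 band tables are carried as editable config following the
  published NPSC structure; a regulatory revision is a config edit.
* The NOVA assignment is a transparent marker-list heuristic (any
  ultra-processed marker → group 4, else any processed marker → group 3,
  else group 1, culinary ingredients omitted), honest about being
  config-driven rather than a re-derivation of the full methodology.
* FVNL and free-sugar estimation are rule-based emulations of expert
  judgement; survey-grade results require survey-grade rule tables.
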