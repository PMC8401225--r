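# scored model

# straight-line re-read of the band config: count bands strictly exceeded
oracle_step_points <- function(value, step, cap) {
  if (is.na(value)) return(0L)
  pts <- 0L
  for (k in seq_len(cap)) if (value > k * step) pts <- k
  pts
}

oracle_score <- function(product, cfg, scoring_category) {
  cap_for <- function(band) {
    if (scoring_category == "cheese_or_fat" && !is.null(band$cap_category3)) {
      band$cap_category3
    } else {
      band$cap
    }
  }
  bl <- cfg$baseline
  baseline <- oracle_step_points(product$energy_kJ, bl$energy_kJ$step,
                                 cap_for(bl$energy_kJ)) +
    oracle_step_points(product$sat_fat_g, bl$sat_fat_g$step, cap_for(bl$sat_fat_g)) +
    oracle_step_points(product$total_sugar_g, bl$total_sugar_g$step,
                       cap_for(bl$total_sugar_g)) +
    oracle_step_points(product$sodium_mg, bl$sodium_mg$step, cap_for(bl$sodium_mg))
  md <- cfg$modifying
  fvnl <- 0L
  for (band in md$fvnl_percent$ladder) {
    if (!is.na(product$fvnl_percent) && product$fvnl_percent > band$above) {
      fvnl <- band$points
    }
  }
  protein <- oracle_step_points(product$protein_g, md$protein_g$step,
                                md$protein_g$cap)
  if (baseline >= cfg$protein_cap$baseline_at_least &&
      fvnl < cfg$protein_cap$min_fvnl_points) {
    protein <- 0L
  }
  fibre <- oracle_step_points(product$fiber_g, md$fiber_g$step, md$fiber_g$cap)
  list(baseline = baseline, final = baseline - protein - fibre - fvnl)
}

test_that("band scoring matches an independent re-read of the config tables", {
  cfg <- sahnc_points_config()
  set.seed(7)
  for (i in 1:40) {
    is_bev <- i %% 3 == 0
    fat <- runif(1, 0, 40)
    p <- make_product(
      paste0("r", i),
      category = if (is_bev) "sodas" else "snack foods",
      form = if (is_bev) "liquid" else "solid",
      energy = runif(1, 0, 4000), sugar = runif(1, 0, 60),
      fat = fat, satfat = runif(1, 0, fat), sodium = runif(1, 0, 2000),
      protein = runif(1, 0, 20), fiber = runif(1, 0, 10),
      fvnl = sample(c(0, 25, 50, 75, 100), 1)
    )
    sc <- score_sahnc(p, variant = "final")
    ora <- oracle_score(p, cfg, sc$scoring_category)
    expect_equal(sc$baseline_points, ora$baseline)
    expect_equal(sc$final_score, ora$final)
  }
})

test_that("an all-zero panel scores zero under both variants", {
  p <- make_product("z", energy = 0, sugar = 0, fat = 0, satfat = 0,
                    sodium = 0, protein = 0, fiber = 0, fvnl = 0)
  expect_equal(score_sahnc(p, variant = "baseline")$final_score, 0L)
  expect_equal(score_sahnc(p, variant = "final")$final_score, 0L)
})

test_that("the final score never exceeds the baseline score", {
  supply <- generate_supply(default_generator_config(seed = 99, n_scale = 0.03))
  final <- score_sahnc(supply, variant = "final")
  baseline <- score_sahnc(supply, variant = "baseline")
  expect_true(all(final$final_score <= baseline$final_score))
  expect_equal(baseline$modifying_points, rep(0L, nrow(supply)))
})

test_that("compliance thresholds are strict per scoring category", {
  expect_true(sahnc_compliant(0, "beverage"))
  expect_false(sahnc_compliant(1, "beverage"))
  expect_true(sahnc_compliant(3, "other"))
  expect_false(sahnc_compliant(4, "other"))
  expect_true(sahnc_compliant(27, "cheese_or_fat"))
  expect_false(sahnc_compliant(28, "cheese_or_fat"))
  expect_error(sahnc_compliant(0, "dessert"), "Unknown scoring category")
})

test_that("the protein-cap rule bars protein points at high baseline scores", {
  # baseline 20 points, protein present, FVNL 0 -> protein points barred
  high <- make_product("h", energy = 3400, sugar = 46, satfat = 11, fat = 12,
                       sodium = 1000, protein = 10, fiber = 0, fvnl = 0)
  sc <- score_sahnc(high, variant = "final")
  expect_gte(sc$baseline_points, 13)
  expect_equal(sc$protein_points, 0L)

  # same product with top FVNL points regains its protein points
  high$fvnl_percent <- 100
  sc2 <- score_sahnc(high, variant = "final")
  expect_gt(sc2$protein_points, 0L)
})

test_that("cheese/fats scoring uses the extended category-3 caps", {
  fatty <- make_product("cf", category = "fats & oils", energy = 3000,
                        sugar = 0, fat = 90, satfat = 25.5, sodium = 0)
  sc <- score_sahnc(fatty, variant = "baseline")
  expect_equal(sc$scoring_category, "cheese_or_fat")
  expect_gt(sc$sat_fat_points, 10)  # beyond the ordinary 10-point cap
  expect_equal(sc$sat_fat_points, 25L)
  expect_false(sc$compliant)        # 33 points fails even the <28 threshold
})
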