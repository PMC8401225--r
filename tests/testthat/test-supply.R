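test_that("category means pool products, and rollups are pooled not averaged", {
  p <- make_products(
    make_product("a", sodium = 100),
    make_product("b", sodium = 300),
    make_product("c", category = "legumes", sodium = 600),
    make_product("d", category = "sodas", form = "liquid", sodium = 20,
                 fat = 0, satfat = 0)
  )
  summ <- summarize_categories(p)
  snack <- summ[summ$category == "snack foods", ]
  expect_equal(snack$mean_sodium_mg, 200)
  food <- summ[summ$level == "food total", ]
  # pooled mean over three food products, not the mean of category means
  expect_equal(food$mean_sodium_mg, round_half_up((100 + 300 + 600) / 3, 1))
  all_row <- summ[summ$level == "food & beverage total", ]
  expect_equal(all_row$n, 4)
})

test_that("means over partly missing nutrients record their divisor", {
  p <- make_products(
    make_product("a", trans = NA),
    make_product("b", trans = NA)
  )
  summ <- summarize_categories(p)
  snack <- summ[summ$category == "snack foods", ]
  expect_true(is.na(snack$mean_trans_fat_g))
  expect_equal(snack$n_nonmissing_trans_fat_g, 0)
  expect_equal(snack$n_nonmissing_sodium_mg, 2)
})

test_that("regulated counts equal a hand tally on a constructed fixture", {
  # ten products with known CWO flag sets
  p <- make_products_list(lapply(1:10, function(i) {
    make_product(paste0("p", i),
      energy = c(1200, 1300, 900, 900, 2000, 900, 900, 1200, 900, 900)[i],
      sugar = c(0, 12, 11, 0, 15, 0, 0, 0, 0, 0)[i],
      satfat = c(0, 0, 0, 5, 5, 0, 0, 0, 0, 0)[i],
      fat = 6,
      sodium = c(0, 0, 0, 0, 500, 450, 0, 0, 0, 0)[i]
    )
  }))
  res <- classify_cwo(p, missing = "error")
  counts <- count_regulated(p, res)
  total <- counts[counts$category == "total", ]
  # hand tally: flagged products are p1..p6 and p8; energy-only p1 and p8
  expect_equal(total$regulated_overall, 7)
  expect_equal(total$regulated_energy, 4)   # p1, p2, p5, p8
  expect_equal(total$regulated_sugar, 3)    # p2, p3, p5
  expect_equal(total$regulated_sat_fat, 2)  # p4, p5
  expect_equal(total$regulated_sodium, 2)   # p5, p6
  expect_equal(total$regulated_energy_only, 2)
})

test_that("union bound holds between overall and per-nutrient counts", {
  supply <- generate_supply(default_generator_config(seed = 3, n_scale = 0.05))
  res <- classify_cwo(supply, missing = "excessive")
  counts <- count_regulated(supply, res)
  total <- counts[counts$category == "total", ]
  per_nutrient <- c(total$regulated_sugar, total$regulated_sodium,
                    total$regulated_sat_fat, total$regulated_energy)
  expect_lte(total$regulated_overall, sum(per_nutrient))
  expect_gte(total$regulated_overall, max(per_nutrient))
  expect_lte(total$regulated_energy_only, total$regulated_energy)
})

test_that("energy-only and per-nutrient shares follow their definitions", {
  expect_equal(energy_only_share(100, 4344), 2.3)
  expect_equal(energy_only_share(0, 50), 0)
  expect_equal(energy_only_share(50, 50), 100)
  expect_error(energy_only_share(1, 0), "positive")

  expect_equal(sugar_compliance_share(385, 3), 99)
  expect_equal(sugar_compliance_share(100, 0), 100)
  expect_equal(sugar_compliance_share(100, 100), 0)
})

test_that("model comparison matches per-model classification on a fixture", {
  supply <- demo_supply()
  cmp <- compare_models(supply)
  overall <- cmp[cmp$category == "overall", ]
  expect_setequal(overall$model,
                  c("cwo2019", "sa_proposed", "sahnc", "sahnc_baseline"))
  # cross-check one model against its classifier
  cwo <- classify_cwo(supply, missing = "excessive")
  expect_equal(overall$compliant_n[overall$model == "cwo2019"],
               sum(cwo$compliant))
  # scored-model nesting
  expect_gte(overall$compliant_n[overall$model == "sahnc"],
             overall$compliant_n[overall$model == "sahnc_baseline"])
})

test_that("comparison totals are invariant to product order", {
  supply <- generate_supply(default_generator_config(seed = 8, n_scale = 0.02))
  shuffled <- supply[rev(seq_len(nrow(supply))), ]
  a <- compare_models(supply, models = c("cwo2019", "sa_proposed"))
  b <- compare_models(shuffled, models = c("cwo2019", "sa_proposed"))
  a <- dplyr::arrange(a, category, model)
  b <- dplyr::arrange(b, category, model)
  expect_equal(a, b)
})

test_that("an all-zero supply is fully compliant under every model", {
  p <- make_products(
    make_product("z1", energy = 0, sugar = 0, fat = 0, satfat = 0, sodium = 0,
                 nss = FALSE),
    make_product("z2", category = "sodas", form = "liquid", energy = 0,
                 sugar = 0, fat = 0, satfat = 0, sodium = 0, nss = FALSE)
  )
  cmp <- compare_models(p)
  expect_true(all(cmp$compliant_pct[cmp$category == "overall"] == 100))
})
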