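# threshold-model classification

test_that("at-limit values are compliant and strict exceedance flags", {
  p <- make_products(
    make_product("at", sodium = 400, sugar = 0, satfat = 0, fat = 0,
                 energy = 100, contains_added_sugar = TRUE),
    make_product("zero", sodium = 0, sugar = 0, satfat = 0, fat = 0,
                 energy = 0.1),
    make_product("liq", category = "sodas", form = "liquid", sodium = 0,
                 sugar = 6.9, free_sugar = 6.9, satfat = 0, fat = 0,
                 energy = 100, contains_added_sugar = TRUE)
  )
  res <- classify_cwo(p, missing = "error")
  expect_true(res$compliant[res$product_id == "at"])
  expect_true(res$compliant[res$product_id == "zero"])
  liq <- res[res$product_id == "liq", ]
  expect_true(liq$flag_sugar)
  expect_false(liq$flag_sodium || liq$flag_sat_fat || liq$flag_energy)
})

test_that("the CWO sugar limit applies only to products with added sugar/salt/satfat", {
  juice <- make_product("j", category = "100% fruit juice", form = "liquid",
                        sugar = 10.4, free_sugar = 6.0, satfat = 0, fat = 0,
                        energy = 190, sodium = 9.5,
                        contains_added_sugar = FALSE,
                        contains_added_sodium = FALSE,
                        contains_added_sat_fat = FALSE)
  res <- classify_cwo(juice, missing = "error")
  expect_false(res$flag_sugar)
  expect_true(res$compliant)

  sweetened <- juice
  sweetened$contains_added_sugar <- TRUE
  expect_true(classify_cwo(sweetened, missing = "error")$flag_sugar)
})

test_that("missing evaluated nutrients demand an explicit policy", {
  p <- make_product("m", sodium = NA)
  expect_error(classify_cwo(p), "policy|excessive")
  expect_true(classify_cwo(p, missing = "excessive")$flag_sodium)
  expect_false(classify_cwo(p, missing = "permissive")$flag_sodium)
})

test_that("proposed-model boundaries match the cut-point table exactly", {
  fx <- fixture_supply("table5_boundaries")
  res <- classify_sa_proposed(fx$products)
  res <- res[match(fx$expected$product_id, res$product_id), ]
  got_flags <- vapply(seq_len(nrow(res)), function(i) {
    fl <- c(sugar = res$flag_sugar[i], sodium = res$flag_sodium[i],
            sat_fat = res$flag_sat_fat[i], nss = res$flag_nss[i])
    paste(names(fl)[fl], collapse = ",")
  }, character(1))
  expect_equal(got_flags, fx$expected$expected_flags)
  expect_equal(res$compliant, fx$expected$expected_compliant)
})

test_that("qualifying criteria gate the proposed model's nutrient limits", {
  rich <- make_product("r", sodium = 900, sugar = 30, satfat = 9, fat = 12,
                       contains_free_sugar_source = FALSE,
                       contains_added_sodium = FALSE,
                       contains_added_sat_fat = FALSE,
                       nss = FALSE)
  res <- classify_sa_proposed(rich)
  expect_true(res$compliant)

  # intrinsic-sugar beverage over the numeric limit stays unflagged
  juice <- make_product("j", category = "100% fruit juice", form = "liquid",
                        sugar = 10.4, free_sugar = 6, satfat = 0, fat = 0,
                        sodium = 9.5, contains_free_sugar_source = FALSE,
                        contains_added_sodium = FALSE,
                        contains_added_sat_fat = FALSE, nss = FALSE)
  expect_false(classify_sa_proposed(juice)$flag_sugar)

  # with all qualifiers present it reduces to a pure threshold model
  rich$contains_free_sugar_source <- TRUE
  rich$contains_added_sodium <- TRUE
  rich$contains_added_sat_fat <- TRUE
  res2 <- classify_sa_proposed(rich)
  expect_true(res2$flag_sugar && res2$flag_sodium && res2$flag_sat_fat)
})

test_that("a missing value in a qualified nutrient is assessed as excessive", {
  p <- make_product("m", sodium = NA, contains_added_sodium = TRUE)
  res <- classify_sa_proposed(p)
  expect_true(res$flag_sodium)
  expect_false(res$compliant)

  # but not when the nutrient is unqualified
  p2 <- make_product("m2", sodium = NA, contains_added_sodium = FALSE)
  expect_false(classify_sa_proposed(p2)$flag_sodium)
})

test_that("classification is invariant to input units after normalisation", {
  p <- make_product("u", sodium = 500, sugar = 12, satfat = 5, fat = 8,
                    energy = 1600)
  alt <- p
  alt$sodium_mg <- alt$sodium_mg / 1000      # supplied in g
  alt$energy_kJ <- alt$energy_kJ / 4.184     # supplied in kcal
  alt <- normalize_units(alt, list(sodium_mg = "g", energy_kJ = "kcal"))
  for (f in c(classify_cwo, classify_sa_proposed)) {
    a <- f(p)
    b <- f(alt)
    expect_equal(a[setdiff(names(a), "detail")], b[setdiff(names(b), "detail")])
  }
})

test_that("raising any evaluated nutrient never removes a flag (monotonicity)", {
  set.seed(42)
  cuts <- thresholds_sa_proposed()
  for (i in 1:25) {
    sodium <- runif(1, 0, 800)
    sugar <- runif(1, 0, 20)
    satfat <- runif(1, 0, 8)
    p <- make_product("m", sodium = sodium, sugar = sugar, satfat = satfat,
                      fat = satfat + 1, nss = FALSE)
    base <- classify_sa_proposed(p)
    bump_col <- sample(c("sodium_mg", "total_sugar_g", "sat_fat_g"), 1)
    bumped <- p
    bumped[[bump_col]] <- bumped[[bump_col]] + runif(1, 0, 500)
    if (bump_col == "sat_fat_g") bumped$total_fat_g <- bumped$sat_fat_g + 1
    if (bump_col == "total_sugar_g") bumped$free_sugar_g <- NA
    after <- classify_sa_proposed(bumped)
    for (fc in c("flag_sugar", "flag_sodium", "flag_sat_fat")) {
      expect_true(after[[fc]] >= base[[fc]])
    }
    expect_true(base$compliant >= after$compliant)
  }
})
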