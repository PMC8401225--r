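# Hand-authored fixtures -----------------------------------------------------
#
# Small supplies with known classifications, used in tests and demos. Each
# fixture returns the products together with the expected results, derived
# by hand from the cut-point definitions when the fixture was authored.

#' Hand-authored fixture supplies
#'
#' * `"table5_boundaries"`: products sitting exactly at, just below and just
#'   above each proposed-NPM cut-point (solids and liquids), all qualifying
#'   criteria present, plus one sweetener-containing product. At-limit
#'   products are compliant (exceed is strict); above-limit products flag.
#' * `"energy_only_demo"`: products around the CWO energy limit, including
#'   one flagged for energy and nothing else.
#' * `"leniency_demo"`: products whose scored-model classification differs
#'   between the baseline and final variants (nutrients to encourage rescue
#'   the final score), plus one where they agree.
#'
#' @param name fixture name.
#' @return a list with elements `products` (validated tibble) and
#'   `expected` (tibble of product_id, model, expected flags/compliance).
#' @export
fixture_supply <- function(name = c("table5_boundaries", "energy_only_demo",
                                    "leniency_demo")) {
  name <- match.arg(name)
  base <- function(id, category, form, energy = 100, sugar = 0, fat = 0,
                   satfat = 0, sodium = 0, protein = NA, fiber = NA,
                   fvnl = NA, ingredients = NA_character_, nss = FALSE) {
    tibble::tibble(
      product_id = id, category = category, form = form,
      basis = "as_packaged", nip_present = TRUE,
      energy_kJ = energy, total_sugar_g = sugar, free_sugar_g = sugar,
      total_fat_g = max(fat, satfat), sat_fat_g = satfat, trans_fat_g = 0,
      sodium_mg = sodium, protein_g = protein, fiber_g = fiber,
      fvnl_percent = fvnl, ingredients_text = ingredients,
      contains_nss = nss,
      contains_free_sugar_source = TRUE, contains_added_sodium = TRUE,
      contains_added_sat_fat = TRUE, contains_added_sugar = TRUE
    )
  }
  if (name == "table5_boundaries") {
    products <- dplyr::bind_rows(
      base("sol-sod-at", "snack foods", "solid", sodium = 400),
      base("sol-sod-over", "snack foods", "solid", sodium = 401),
      base("sol-sug-at", "snack foods", "solid", sugar = 10),
      base("sol-sug-over", "snack foods", "solid", sugar = 10.5),
      base("sol-sat-at", "snack foods", "solid", satfat = 4),
      base("sol-sat-over", "snack foods", "solid", satfat = 4.5),
      base("liq-sod-at", "other beverages", "liquid", sodium = 100),
      base("liq-sod-over", "other beverages", "liquid", sodium = 101),
      base("liq-sug-at", "other beverages", "liquid", sugar = 5),
      base("liq-sug-over", "other beverages", "liquid", sugar = 6.9),
      base("liq-sat-at", "other beverages", "liquid", satfat = 3),
      base("liq-sat-over", "other beverages", "liquid", satfat = 3.5),
      base("liq-nss", "other beverages", "liquid",
           ingredients = "carbonated water, sucralose", nss = TRUE),
      base("sol-clean", "snack foods", "solid")
    )
    expected <- tibble::tibble(
      product_id = products$product_id,
      model = "sa_proposed",
      expected_flags = c("", "sodium", "", "sugar", "", "sat_fat",
                         "", "sodium", "", "sugar", "", "sat_fat",
                         "nss", ""),
      expected_compliant = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                             TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                             FALSE, TRUE)
    )
  } else if (name == "energy_only_demo") {
    products <- dplyr::bind_rows(
      base("energy-only", "snack foods", "solid", energy = 1200),
      base("energy-and-sugar", "snack foods", "solid", energy = 1300, sugar = 12),
      base("under-everything", "snack foods", "solid", energy = 900)
    )
    expected <- tibble::tibble(
      product_id = products$product_id,
      model = "cwo2019",
      expected_flags = c("energy", "energy,sugar", ""),
      expected_compliant = c(FALSE, FALSE, TRUE)
    )
  } else {
    products <- dplyr::bind_rows(
      # baseline 4 points from energy; 5 fibre points rescue the final score
      base("rescued-by-fibre", "breakfast cereals", "solid", energy = 1400,
           protein = 0, fiber = 5, fvnl = 0),
      # scores 0 either way
      base("plain-water", "other beverages", "liquid", energy = 1,
           protein = 0, fiber = 0, fvnl = 0),
      # sweet soda: no nutrients to encourage, variants agree
      base("sweet-soda", "sodas", "liquid", energy = 180, sugar = 10,
           protein = 0, fiber = 0, fvnl = 0)
    )
    expected <- tibble::tibble(
      product_id = products$product_id,
      model = c("sahnc_vs_baseline", "sahnc_vs_baseline", "sahnc_vs_baseline"),
      expected_compliant_baseline = c(FALSE, TRUE, FALSE),
      expected_compliant_final = c(TRUE, TRUE, FALSE)
    )
  }
  list(products = validate_products(products), expected = expected)
}
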