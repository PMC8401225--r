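# shared builders for small product tables

make_product <- function(id = "p1", category = "snack foods", form = "solid",
                         energy = 500, sugar = 2, free_sugar = NA,
                         fat = 5, satfat = 1, trans = 0, sodium = 100,
                         protein = NA, fiber = NA, fvnl = NA,
                         ingredients = NA_character_, nss = NA, ...) {
  tibble::tibble(
    product_id = id, category = category, form = form,
    basis = "as_packaged", nip_present = TRUE,
    energy_kJ = energy, total_sugar_g = sugar, free_sugar_g = free_sugar,
    total_fat_g = fat, sat_fat_g = satfat, trans_fat_g = trans,
    sodium_mg = sodium, protein_g = protein, fiber_g = fiber,
    fvnl_percent = fvnl, ingredients_text = ingredients, contains_nss = nss,
    ...
  )
}

make_products <- function(...) dplyr::bind_rows(...)

# a small clean mixed supply used by several tests
demo_supply <- function() {
  make_products(
    make_product("f1", "snack foods", sodium = 500, sugar = 12, satfat = 5,
                 fat = 8, energy = 1600),
    make_product("f2", "legumes", sodium = 100, sugar = 1, satfat = 0.1,
                 fat = 0.5, energy = 300,
                 ingredients = "chickpeas, water, salt"),
    make_product("b1", "sodas", form = "liquid", sodium = 15, sugar = 9,
                 satfat = 0, fat = 0, energy = 160,
                 ingredients = "carbonated water, sugar, flavouring"),
    make_product("b2", "other beverages", form = "liquid", sodium = 10,
                 sugar = 0.5, satfat = 0, fat = 0, energy = 20,
                 ingredients = "water, sucralose, flavouring")
  )
}

make_products_list <- function(lst) dplyr::bind_rows(lst)
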