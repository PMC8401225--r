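# Sugar guideline arithmetic and free-sugar estimation ------------------------

#' WHO-aligned sugar guideline constants
#'
#' Built on a reference intake of 8400 kJ/day: at most 10% of energy from
#' total sugar and 5% from free sugar, i.e. 1 g of total sugar per 168 kJ and
#' 1 g of free sugar per 336 kJ consumed. Percent-of-energy arithmetic uses a
#' sugar energy density of 17 kJ/g. Note the deliberate internal tension:
#' the 168 kJ/g anchor implies 16.8 kJ/g (8400 kJ / 50 g), but reported
#' %-energy figures follow the 17 kJ/g label convention; each constant is
#' used exactly where the reporting convention uses it.
#'
#' @return named list of constants.
#' @export
sugar_constants <- function() {
  list(
    reference_energy_kJ_per_day = 8400,
    total_sugar_energy_share = 0.10,
    free_sugar_energy_share = 0.05,
    kJ_per_g_total_anchor = 168,
    kJ_per_g_free_anchor = 336,
    sugar_energy_density_kJ_per_g = 17
  )
}

#' WHO-aligned sugar limit for a given energy density
#'
#' For food with mean energy density `mean_energy` (kJ per 100 g or 100 mL),
#' the sugar content aligned with WHO dietary guidelines is
#' `mean_energy / 168` g total sugar (or `mean_energy / 336` g free sugar)
#' per 100 g/mL.
#'
#' @param mean_energy kJ per 100 g (solids) or 100 mL (liquids); must be
#'   positive.
#' @param sugar_kind `"total"` or `"free"`.
#' @param constants guideline constants; see [sugar_constants()].
#' @param digits rounding (half-up), default 1 decimal place.
#' @return grams per 100 g/mL.
#' @export
#' @examples
#' who_aligned_limit(1072.8, "total") # 6.4 g/100 g
#' who_aligned_limit(160.7, "free")   # 0.5 g/100 mL
who_aligned_limit <- function(mean_energy, sugar_kind = c("total", "free"),
                              constants = sugar_constants(), digits = 1) {
  sugar_kind <- match.arg(sugar_kind)
  if (any(!is.finite(mean_energy)) || any(mean_energy <= 0)) {
    abort("`mean_energy` must be positive.")
  }
  anchor <- if (sugar_kind == "total") {
    constants$kJ_per_g_total_anchor
  } else {
    constants$kJ_per_g_free_anchor
  }
  round_half_up(mean_energy / anchor, digits)
}

#' Percent of energy attributable to sugar
#'
#' `100 * sugar_g * 17 / energy_kJ`, using the 17 kJ/g sugar energy density
#' of label arithmetic, rounded half-up to 1 decimal place. A sugar energy
#' exceeding the declared total energy indicates a data inconsistency and
#' raises a warning, but the value is still returned.
#'
#' @param sugar_g grams of sugar per 100 g/mL.
#' @param energy_kJ kJ per 100 g/mL; must be positive.
#' @param constants guideline constants.
#' @param digits rounding (half-up).
#' @return percent of energy.
#' @export
#' @examples
#' pct_energy_from_sugar(13.4, 1072.8) # 21.2
#' pct_energy_from_sugar(7.2, 160.7)   # 76.2
pct_energy_from_sugar <- function(sugar_g, energy_kJ,
                                  constants = sugar_constants(), digits = 1) {
  if (any(!is.finite(energy_kJ)) || any(energy_kJ <= 0)) {
    abort("`energy_kJ` must be positive.")
  }
  dens <- constants$sugar_energy_density_kJ_per_g
  if (any(sugar_g * dens > energy_kJ + 1e-9)) {
    warn("Sugar energy exceeds total energy for at least one input (data inconsistency).")
  }
  round_half_up(100 * sugar_g * dens / energy_kJ, digits)
}

#' Default free-sugar estimation rules
#'
#' Category rules in the spirit of the PAHO estimation approach: sugar in
#' sodas and similar formulated products is entirely free; intrinsic sugar
#' (lactose in plain dairy, sugar inside intact fruit/vegetable/legume
#' tissue) is not free; mixed categories can be given fractional rules.
#' Sugars in 100% fruit juice count as free under the WHO definition. The
#' rules are an editable YAML table so survey-specific rules can be dropped
#' in.
#'
#' @return named list: category -> list(type = "all_free" | "none_free" |
#'   "fraction", fraction = numeric).
#' @export
default_free_sugar_rules <- function() {
  read_pkg_yaml("free_sugar_rules.yaml")
}

#' Estimate free sugar where not declared
#'
#' Returns the declared `free_sugar_g` unchanged when present; otherwise
#' applies the category rule to `total_sugar_g`. The estimate never exceeds
#' total sugar.
#'
#' @param products product tibble with `category`, `total_sugar_g` and
#'   optionally `free_sugar_g`.
#' @param rules rule table; see [default_free_sugar_rules()].
#' @return a tibble with columns `free_sugar_g` and `free_sugar_source`
#'   (`"declared"` or `"estimated"`).
#' @export
#' @examples
#' p <- tibble::tibble(
#'   product_id = "s", category = "sodas", form = "liquid",
#'   energy_kJ = 125, total_sugar_g = 6.9, total_fat_g = 0,
#'   sat_fat_g = 0, sodium_mg = 10
#' )
#' estimate_free_sugar(p)
estimate_free_sugar <- function(products, rules = default_free_sugar_rules()) {
  total <- products$total_sugar_g
  declared <- products[["free_sugar_g"]] %||% rep(NA_real_, nrow(products))
  uncovered <- setdiff(unique(products$category[is.na(declared)]), names(rules))
  if (length(uncovered)) {
    abort(paste0("No free-sugar rule for categor",
                 if (length(uncovered) > 1) "ies: " else "y: ",
                 paste(uncovered, collapse = ", ")))
  }
  est <- vapply(seq_len(nrow(products)), function(i) {
    if (!is.na(declared[i])) return(declared[i])
    rule <- rules[[products$category[i]]]
    if (is.na(total[i])) return(NA_real_)
    switch(rule$type,
      all_free = total[i],
      none_free = 0,
      fraction = min(total[i], rule$fraction * total[i]),
      abort(paste0("Unknown free-sugar rule type: ", rule$type))
    )
  }, numeric(1))
  tibble::tibble(
    free_sugar_g = ifelse(is.na(total), est, pmin(est, total)),
    free_sugar_source = ifelse(is.na(declared), "estimated", "declared")
  )
}
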