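# SA HNC (FSANZ-style) scored model -------------------------------------------
#
# The South African health-and-nutrition-claims model scores baseline points
# for nutrients to limit (energy, saturated fat, total sugar, sodium) and, in
# its final variant, subtracts modifying points for nutrients to encourage
# (protein, fibre, FVNL). The band tables are regulatory config (draft
# R429 / FSANZ NPSC structure), shipped as editable YAML and treated as
# opaque by the engine.

#' Load the points-band configuration
#'
#' @param path YAML config; defaults to the shipped FSANZ/NPSC-style tables.
#' @return a list with `baseline`, `modifying`, `protein_cap`, and
#'   `compliance` threshold entries.
#' @export
sahnc_points_config <- function(path = NULL) {
  cfg <- if (is.null(path)) read_pkg_yaml("sahnc_points.yaml") else yaml::read_yaml(path)
  need <- c("baseline", "modifying", "compliance")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    abort(paste0("Points config is missing section(s): ",
                 paste(missing, collapse = ", ")))
  }
  cfg
}

# points for a stepped band table: n points when value strictly exceeds
# n * step, capped
step_points <- function(value, step, cap) {
  value <- ifelse(is.na(value), 0, value)
  k <- floor(value / step + sqrt(.Machine$double.eps))
  at_boundary <- abs(value - k * step) <= sqrt(.Machine$double.eps) * pmax(1, value)
  k <- ifelse(at_boundary & k > 0, k - 1, k)
  pmin(as.integer(k), as.integer(cap))
}

# points for an explicit threshold ladder (e.g. FVNL: 1/2/5 points above
# 40/60/80 percent)
ladder_points <- function(value, ladder) {
  value <- ifelse(is.na(value), 0, value)
  pts <- numeric(length(value))
  for (band in ladder) {
    pts <- ifelse(value > band$above, band$points, pts)
  }
  as.integer(pts)
}

band_cap <- function(band, scoring_category) {
  if (scoring_category == "cheese_or_fat" && !is.null(band$cap_category3)) {
    band$cap_category3
  } else {
    band$cap
  }
}

#' Score products under the SA HNC model
#'
#' Baseline points accumulate from the energy, saturated-fat, total-sugar and
#' sodium band tables. The final variant subtracts modifying points for
#' protein, fibre and FVNL content (subject to the config's protein-cap rule:
#' above the configured baseline score, protein points count only when the
#' FVNL points reach the configured minimum). The baseline variant awards no
#' modifying points.
#'
#' @param products validated product tibble; `protein_g`, `fiber_g` and
#'   `fvnl_percent` are used when present (missing values score 0 modifying
#'   points).
#' @param config points-band configuration; see [sahnc_points_config()].
#' @param variant `"final"` or `"baseline"`.
#' @param taxonomy category taxonomy (supplies the scoring category:
#'   beverage, cheese_or_fat or other). A product column `sahnc_category`
#'   overrides the taxonomy.
#' @return a tibble with one row per product: `baseline_points`, the three
#'   modifying components, `modifying_points`, `final_score`,
#'   `scoring_category` and `compliant`.
#' @export
score_sahnc <- function(products, config = sahnc_points_config(),
                        variant = c("final", "baseline"),
                        taxonomy = default_taxonomy()) {
  variant <- match.arg(variant)
  products <- prefer_basis(validate_products(products, taxonomy = taxonomy))
  scoring_category <- products[["sahnc_category"]] %||%
    taxonomy_lookup(taxonomy, products$category, "sahnc_category")

  bl <- config$baseline
  base_pts <- function(colname, band_name) {
    v <- products[[colname]] %||% rep(NA_real_, nrow(products))
    band <- bl[[band_name]]
    vapply(seq_along(v), function(i) {
      step_points(v[i], band$step, band_cap(band, scoring_category[i]))
    }, integer(1))
  }
  p_energy <- base_pts("energy_kJ", "energy_kJ")
  p_satfat <- base_pts("sat_fat_g", "sat_fat_g")
  p_sugar <- base_pts("total_sugar_g", "total_sugar_g")
  p_sodium <- base_pts("sodium_mg", "sodium_mg")
  baseline_points <- p_energy + p_satfat + p_sugar + p_sodium

  md <- config$modifying
  p_protein <- step_points(products[["protein_g"]] %||% rep(NA_real_, nrow(products)),
                           md$protein_g$step, md$protein_g$cap)
  p_fibre <- step_points(products[["fiber_g"]] %||% rep(NA_real_, nrow(products)),
                         md$fiber_g$step, md$fiber_g$cap)
  p_fvnl <- ladder_points(products[["fvnl_percent"]] %||% rep(NA_real_, nrow(products)),
                          md$fvnl_percent$ladder)

  cap_rule <- config$protein_cap
  if (!is.null(cap_rule)) {
    barred <- baseline_points >= cap_rule$baseline_at_least &
      p_fvnl < cap_rule$min_fvnl_points
    p_protein[barred] <- 0L
  }

  modifying_points <- if (variant == "baseline") {
    rep(0L, nrow(products))
  } else {
    p_protein + p_fibre + p_fvnl
  }

  res <- tibble::tibble(
    product_id = products$product_id,
    category = products$category,
    model = paste0("sahnc_", variant),
    scoring_category = scoring_category,
    energy_points = p_energy,
    sat_fat_points = p_satfat,
    sugar_points = p_sugar,
    sodium_points = p_sodium,
    baseline_points = as.integer(baseline_points),
    protein_points = if (variant == "baseline") 0L else as.integer(p_protein),
    fiber_points = if (variant == "baseline") 0L else as.integer(p_fibre),
    fvnl_points = if (variant == "baseline") 0L else as.integer(p_fvnl),
    modifying_points = as.integer(modifying_points),
    final_score = as.integer(baseline_points - modifying_points)
  )
  res$compliant <- sahnc_compliant(res$final_score, res$scoring_category, config)
  res
}

#' SA HNC compliance from a final score
#'
#' A product may carry a claim (is compliant) when its final score is
#' strictly below the category threshold: less than 1 for beverages, less
#' than 28 for processed cheese and fats, less than 4 for other foods.
#'
#' @param score numeric final score(s).
#' @param scoring_category `"beverage"`, `"cheese_or_fat"` or `"other"`.
#' @param config points configuration holding the `compliance` thresholds.
#' @return logical vector.
#' @export
#' @examples
#' sahnc_compliant(c(0, 4, 27), c("beverage", "other", "cheese_or_fat"))
sahnc_compliant <- function(score, scoring_category,
                            config = sahnc_points_config()) {
  scoring_category <- rep_len(scoring_category, length(score))
  bad <- scoring_category %!in% names(config$compliance)
  if (any(bad)) {
    abort(paste0("Unknown scoring category: ",
                 paste(unique(scoring_category[bad]), collapse = ", ")))
  }
  limit <- vapply(scoring_category, function(sc) config$compliance[[sc]],
                  numeric(1), USE.NAMES = FALSE)
  score < limit
}
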