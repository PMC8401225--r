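# Supply-level analysis -------------------------------------------------------

#' Category-level nutrient summaries
#'
#' Per-category counts, mean nutrient content (computed over non-missing
#' declarations, with the divisor recorded) and NSS prevalence, plus pooled
#' rollup rows for all foods, all beverages and the whole supply. Rollups are
#' pooled means over products, never means of category means.
#'
#' @param products validated product tibble.
#' @param taxonomy category taxonomy.
#' @param digits decimal places for means (half-up); `NULL` leaves them
#'   unrounded.
#' @return a tibble with a `level` column (`"category"`, `"food total"`,
#'   `"beverage total"`, `"food & beverage total"`), `n`, `mean_*` and
#'   `n_nonmissing_*` columns per nutrient, `nss_count`, `nss_pct`.
#' @export
summarize_categories <- function(products, taxonomy = default_taxonomy(),
                                 digits = 1) {
  products <- validate_products(products, taxonomy = taxonomy)
  nutrients <- intersect(
    c("energy_kJ", "total_sugar_g", "free_sugar_g", "total_fat_g",
      "sat_fat_g", "trans_fat_g", "sodium_mg"),
    names(products)
  )
  flags <- products[["contains_nss"]]
  if (is.null(flags) && !is.null(products[["ingredients_text"]])) {
    flags <- vapply(products[["ingredients_text"]], function(tx) {
      isTRUE(detect_nss(tx)$contains_nss)
    }, logical(1), USE.NAMES = FALSE)
  }
  if (is.null(flags)) flags <- rep(NA, nrow(products))
  products$.nss <- !is.na(flags) & flags

  one_group <- function(df, label, level) {
    row <- tibble::tibble(level = level, category = label, n = nrow(df))
    for (nu in nutrients) {
      v <- df[[nu]]
      k <- sum(!is.na(v))
      m <- if (k > 0) mean(v, na.rm = TRUE) else NA_real_
      if (!is.null(digits) && !is.na(m)) m <- round_half_up(m, digits)
      row[[paste0("mean_", nu)]] <- m
      row[[paste0("n_nonmissing_", nu)]] <- k
    }
    row$nss_count <- sum(df$.nss)
    row$nss_pct <- share_pct(sum(df$.nss), nrow(df))
    row
  }

  is_bev <- taxonomy_lookup(taxonomy, products$category, "is_beverage")
  per_cat <- products |>
    dplyr::group_by(.data$category) |>
    dplyr::group_map(~ one_group(.x, .y$category, "category")) |>
    dplyr::bind_rows()
  rollups <- dplyr::bind_rows(
    if (any(!is_bev)) one_group(products[!is_bev, ], "food total", "food total"),
    if (any(is_bev)) one_group(products[is_bev, ], "beverage total", "beverage total"),
    one_group(products, "food & beverage total", "food & beverage total")
  )
  dplyr::bind_rows(per_cat, rollups)
}

#' Regulated counts under a threshold model
#'
#' Tallies, per category and in total, how many products would be regulated
#' (flagged on at least one nutrient), how many per nutrient, and how many
#' for energy but no other nutrient.
#'
#' @param products validated product tibble.
#' @param results a classification result tibble (from [classify_cwo()] or
#'   [classify_sa_proposed()]) covering every product.
#' @return a tibble with one row per category plus a `"total"` row: `n`,
#'   `regulated_overall`, `regulated_<nutrient>` columns, and
#'   `regulated_energy_only` when the model evaluates energy.
#' @export
count_regulated <- function(products, results) {
  if (!all(products$product_id %in% results$product_id)) {
    abort("Every product must appear in `results`.")
  }
  results <- results[match(products$product_id, results$product_id), ]
  flag_cols <- grep("^flag_", names(results), value = TRUE)
  df <- tibble::tibble(category = products$category)
  for (fc in flag_cols) df[[sub("^flag_", "regulated_", fc)]] <- isTRUE_vec(results[[fc]])
  any_flag <- Reduce(`|`, lapply(flag_cols, function(fc) isTRUE_vec(results[[fc]])))
  df$regulated_overall <- any_flag
  if ("flag_energy" %in% flag_cols) {
    others <- setdiff(flag_cols, "flag_energy")
    any_other <- if (length(others)) {
      Reduce(`|`, lapply(others, function(fc) isTRUE_vec(results[[fc]])))
    } else {
      rep(FALSE, nrow(results))
    }
    df$regulated_energy_only <- isTRUE_vec(results$flag_energy) & !any_other
  }
  count_cols <- setdiff(names(df), "category")
  per_cat <- df |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(count_cols), sum),
                     .groups = "drop")
  total <- df |>
    dplyr::summarise(category = "total", n = dplyr::n(),
                     dplyr::across(dplyr::all_of(count_cols), sum))
  dplyr::bind_rows(per_cat, total)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Share of regulated products that exceed only the energy limit
#'
#' @param counts either a regulated-counts tibble from [count_regulated()]
#'   (category rows are summed) or the energy-only count itself.
#' @param regulated_overall total regulated count, when `counts` is given as
#'   a number.
#' @param digits decimal places (half-up).
#' @return percent of regulated products flagged for energy and nothing else.
#' @export
#' @examples
#' energy_only_share(100, 4344) # 2.3
energy_only_share <- function(counts, regulated_overall = NULL, digits = 1) {
  if (is.data.frame(counts)) {
    rows <- counts[counts$category != "total", , drop = FALSE]
    if (!nrow(rows)) rows <- counts
    eo <- sum(rows$regulated_energy_only)
    reg <- sum(rows$regulated_overall)
  } else {
    eo <- counts
    reg <- regulated_overall
  }
  if (is.null(reg) || reg <= 0) abort("Total regulated count must be positive.")
  share_pct(eo, reg, digits)
}

#' Per-nutrient compliance share
#'
#' Percentage of a category's products that do not exceed a given nutrient's
#' limit: `100 * (n - regulated_for_nutrient) / n`.
#'
#' @param n category size.
#' @param regulated_for_nutrient count of products flagged for the nutrient.
#' @param digits decimal places (half-up); default 0, matching the
#'   whole-percent convention of per-nutrient compliance statements.
#' @return percent compliant.
#' @export
#' @examples
#' sugar_compliance_share(385, 3) # 99
sugar_compliance_share <- function(n, regulated_for_nutrient, digits = 0) {
  if (any(n <= 0)) abort("`n` must be positive.")
  share_pct(n - regulated_for_nutrient, n, digits)
}

#' Compare compliance across profiling models
#'
#' Classifies a supply under each requested model and tabulates compliant
#' counts and percentages per category and overall. The scored model's final
#' variant can only be more lenient than its baseline variant, so its
#' compliant set is always a superset.
#'
#' @param products validated product tibble.
#' @param models character vector from `"cwo2019"`, `"sa_proposed"`,
#'   `"sahnc"`, `"sahnc_baseline"`.
#' @param taxonomy category taxonomy.
#' @param cwo_missing missing-value policy forwarded to [classify_cwo()].
#' @param ... further arguments forwarded to the classifiers.
#' @return a tibble: `category` (including `"overall"`), `model`, `n`,
#'   `compliant_n`, `compliant_pct`.
#' @export
compare_models <- function(products,
                           models = c("cwo2019", "sa_proposed",
                                      "sahnc", "sahnc_baseline"),
                           taxonomy = default_taxonomy(),
                           cwo_missing = "excessive", ...) {
  models <- match.arg(models, several.ok = TRUE)
  products <- prefer_basis(validate_products(products, taxonomy = taxonomy))
  compliant_by_model <- list()
  for (m in models) {
    compliant_by_model[[m]] <- switch(
      m,
      cwo2019 = classify_cwo(products, missing = cwo_missing, ...)$compliant,
      sa_proposed = classify_sa_proposed(products, ...)$compliant,
      sahnc = score_sahnc(products, variant = "final",
                          taxonomy = taxonomy)$compliant,
      sahnc_baseline = score_sahnc(products, variant = "baseline",
                                   taxonomy = taxonomy)$compliant
    )
  }
  out <- purrr::imap(compliant_by_model, function(comp, m) {
    df <- tibble::tibble(category = products$category, compliant = comp)
    per_cat <- df |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(n = dplyr::n(), compliant_n = sum(.data$compliant),
                       .groups = "drop")
    overall <- df |>
      dplyr::summarise(category = "overall", n = dplyr::n(),
                       compliant_n = sum(.data$compliant))
    dplyr::bind_rows(per_cat, overall) |>
      dplyr::mutate(model = m,
                    compliant_pct = share_pct(.data$compliant_n, .data$n))
  })
  dplyr::bind_rows(out) |>
    dplyr::select("category", "model", "n", "compliant_n", "compliant_pct")
}
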