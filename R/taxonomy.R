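#' Category taxonomy for the packaged-food supply
#'
#' The supply is divided into 15 sub-categories: 11 food categories
#' (breakfast cereals, cereals & cereal products, confectionery & dessert,
#' dairy, fruits & vegetables, vegetables, legumes, mixed dishes, protein,
#' snack foods, soups & sauces) and 4 beverage categories (dairy drinks,
#' other beverages, sodas, 100% fruit juice). Each category carries whether
#' it is a beverage (which fixes the physical form and the threshold column
#' that applies) and whether products in it can contain fruit, vegetable,
#' nut or legume (FVNL) ingredients; categories such as fats and oils that
#' cannot contain FVNLs always score an FVNL percentage of 0.
#'
#' `fruits & vegetables` and `vegetables` are kept as distinct sub-categories
#' with a shared `parent` (`fruits & vegetables (all)`) so that summaries can
#' be rolled up either way.
#'
#' @param extra optional tibble of additional categories with columns
#'   `category`, `is_beverage`, `fvnl_eligible` (and optionally `parent`,
#'   `sahnc_category`).
#' @return a tibble with columns `category`, `is_beverage`, `fvnl_eligible`,
#'   `parent`, `sahnc_category`.
#' @export
#' @examples
#' default_taxonomy()
default_taxonomy <- function(extra = NULL) {
  tax <- tibble::tribble(
    ~category,                    ~is_beverage, ~fvnl_eligible,
    "breakfast cereals",          FALSE,        TRUE,
    "cereals & cereal products",  FALSE,        TRUE,
    "confectionery & dessert",    FALSE,        TRUE,
    "dairy",                      FALSE,        FALSE,
    "fruits & vegetables",        FALSE,        TRUE,
    "vegetables",                 FALSE,        TRUE,
    "legumes",                    FALSE,        TRUE,
    "mixed dishes",               FALSE,        TRUE,
    "protein",                    FALSE,        TRUE,
    "snack foods",                FALSE,        TRUE,
    "soups & sauces",             FALSE,        TRUE,
    "fats & oils",                FALSE,        FALSE,
    "dairy drinks",               TRUE,         FALSE,
    "other beverages",            TRUE,         TRUE,
    "sodas",                      TRUE,         FALSE,
    "100% fruit juice",           TRUE,         TRUE
  )
  tax$parent <- ifelse(
    tax$category %in% c("fruits & vegetables", "vegetables"),
    "fruits & vegetables (all)", tax$category
  )
  tax$sahnc_category <- ifelse(
    tax$is_beverage, "beverage",
    ifelse(tax$category == "fats & oils", "cheese_or_fat", "other")
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    need <- c("category", "is_beverage", "fvnl_eligible")
    if (!all(need %in% names(extra))) {
      abort(paste0("`extra` must have columns: ", paste(need, collapse = ", ")))
    }
    if (is.null(extra$parent)) extra$parent <- extra$category
    if (is.null(extra$sahnc_category)) {
      extra$sahnc_category <- ifelse(extra$is_beverage, "beverage", "other")
    }
    tax <- dplyr::bind_rows(tax, extra[names(tax)])
  }
  if (anyDuplicated(tax$category)) abort("Duplicate category in taxonomy.")
  tax
}

#' The 15 supply sub-categories used in the 2018 SA survey summaries
#'
#' @return character vector of category names (11 food, 4 beverage).
#' @export
supply_categories <- function() {
  setdiff(default_taxonomy()$category, "fats & oils")
}

taxonomy_lookup <- function(taxonomy, categories, what) {
  idx <- match(categories, taxonomy$category)
  if (anyNA(idx)) {
    bad <- unique(categories[is.na(idx)])
    abort(paste0(
      "Unknown categor", if (length(bad) > 1) "ies: " else "y: ",
      paste(bad, collapse = ", "),
      ". Allowed: ", paste(taxonomy$category, collapse = ", ")
    ))
  }
  taxonomy[[what]][idx]
}
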