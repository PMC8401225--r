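# Product tables -------------------------------------------------------------
#
# A product table holds one packaged food or beverage per row, with the
# nutrient declaration from its nutrition information panel (NIP) on a
# per-100 g (solids) or per-100 mL (liquids) basis. Missing declarations are
# first-class NA values, never zeros: the proposed model's
# missing-defaults-to-excessive rule depends on knowing a value is absent.

NUTRIENT_COLS <- c(
  "energy_kJ", "total_sugar_g", "free_sugar_g", "total_fat_g", "sat_fat_g",
  "trans_fat_g", "sodium_mg", "protein_g", "fiber_g", "fvnl_percent"
)

REQUIRED_COLS <- c(
  "product_id", "category", "form",
  "energy_kJ", "total_sugar_g", "total_fat_g", "sat_fat_g", "sodium_mg"
)

QUALIFIER_COLS <- c(
  "contains_free_sugar_source", "contains_added_sodium",
  "contains_added_sat_fat", "contains_nss", "contains_added_sugar"
)

#' Read a product table from delimited text
#'
#' Reads a UTF-8 delimited file (comma by default, tab accepted) with one
#' product per row. Required columns: `product_id`, `category`, `form`,
#' `energy_kJ`, `total_sugar_g`, `total_fat_g`, `sat_fat_g`, `sodium_mg`.
#' Optional columns: the remaining nutrients, `basis`, `nip_present`,
#' `ingredients_text` and ingredient-derived qualifier flags. Empty cells are
#' missing values; non-numeric text in a nutrient cell (e.g. `"n/a"`) becomes
#' `NA` with a warning, never a silent zero.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` (default) picks tab when the file name
#'   ends in `.tsv`, comma otherwise.
#' @param taxonomy category taxonomy used for validation; see
#'   [default_taxonomy()].
#' @return validated product tibble (see [validate_products()]).
#' @export
read_products <- function(path, delim = NULL, taxonomy = default_taxonomy()) {
  if (!file.exists(path)) abort(paste0("Product file not found: ", path))
  delim <- delim %||% (if (grepl("\\.tsv$", path)) "\t" else ",")
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing_cols)) {
    abort(paste0(
      "Product table is missing required column",
      if (length(missing_cols) > 1) "s" else "", ": ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- raw
  for (col in intersect(c(NUTRIENT_COLS), names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & is.na(parsed)
    if (any(bad)) {
      warn(paste0(
        "Column `", col, "`: ", sum(bad), " non-numeric cell",
        if (sum(bad) > 1) "s" else "", " (e.g. \"", raw[[col]][which(bad)[1]],
        "\") treated as missing."
      ))
    }
    out[[col]] <- parsed
  }
  for (col in intersect(c("nip_present", QUALIFIER_COLS), names(raw))) {
    out[[col]] <- as.logical(raw[[col]])
  }
  if (is.null(out[["basis"]])) out[["basis"]] <- "as_packaged"
  if (is.null(out[["nip_present"]])) out[["nip_present"]] <- TRUE
  out[["basis"]][is.na(out[["basis"]])] <- "as_packaged"
  validate_products(out, taxonomy = taxonomy)
}

#' Write a product table to delimited text
#'
#' @param products product tibble.
#' @param path output path; `.tsv` extension selects tab delimiting.
#' @param delim optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_products <- function(products, path, delim = NULL) {
  delim <- delim %||% (if (grepl("\\.tsv$", path)) "\t" else ",")
  readr::write_delim(products, path, delim = delim, na = "")
  invisible(path)
}

#' Validate a product table
#'
#' Checks the schema and the panel invariants: all declared amounts are
#' non-negative; saturated and trans fat never exceed total fat; free sugar
#' never exceeds total sugar; FVNL percentage lies in \[0, 100\]; every
#' category is in the taxonomy; beverages are liquid and foods solid; at most
#' one row per `product_id` and `basis`.
#'
#' @param products product tibble.
#' @param taxonomy category taxonomy.
#' @return the validated tibble, invisibly classed as-is.
#' @export
validate_products <- function(products, taxonomy = default_taxonomy()) {
  products <- tibble::as_tibble(products)
  missing_cols <- setdiff(REQUIRED_COLS, names(products))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  is_bev <- taxonomy_lookup(taxonomy, products$category, "is_beverage")
  if (any(products$form %!in% c("solid", "liquid"))) {
    abort("`form` must be \"solid\" or \"liquid\".")
  }
  mismatch <- (is_bev & products$form != "liquid") |
    (!is_bev & products$form != "solid")
  if (any(mismatch)) {
    abort(paste0(
      "Category/form mismatch for product(s): ",
      paste(head(products$product_id[mismatch], 5), collapse = ", "),
      " (beverage categories must be liquid, food categories solid)."
    ))
  }
  if (!is.null(products[["basis"]]) &&
      any(products[["basis"]] %!in% c("as_packaged", "as_consumed"))) {
    abort("`basis` must be \"as_packaged\" or \"as_consumed\".")
  }
  key <- paste(products$product_id, products[["basis"]] %||% "as_packaged")
  if (anyDuplicated(key)) abort("Duplicate product_id/basis rows.")
  for (col in intersect(NUTRIENT_COLS, names(products))) {
    v <- products[[col]]
    if (any(v < 0, na.rm = TRUE)) abort(paste0("Negative values in `", col, "`."))
  }
  chk <- function(a, b, msg) {
    bad <- !is.na(products[[a]]) & !is.na(products[[b]]) &
      products[[a]] > products[[b]] + 1e-9
    if (any(bad)) abort(paste0(msg, " (product ",
                               products$product_id[which(bad)[1]], ")."))
  }
  if (all(c("sat_fat_g", "total_fat_g") %in% names(products))) {
    chk("sat_fat_g", "total_fat_g", "Saturated fat exceeds total fat")
  }
  if (all(c("trans_fat_g", "total_fat_g") %in% names(products))) {
    chk("trans_fat_g", "total_fat_g", "Trans fat exceeds total fat")
  }
  if (all(c("free_sugar_g", "total_sugar_g") %in% names(products))) {
    chk("free_sugar_g", "total_sugar_g", "Free sugar exceeds total sugar")
  }
  if (!is.null(products[["fvnl_percent"]]) &&
      any(products[["fvnl_percent"]] > 100, na.rm = TRUE)) {
    abort("`fvnl_percent` must lie in [0, 100].")
  }
  products
}

#' Normalise nutrient columns to canonical units
#'
#' Canonical units are grams per 100 g/mL for all nutrients except sodium
#' (milligrams) and energy (kilojoules). `unit_spec` names the unit each
#' column arrives in (`"g"`, `"mg"`, `"kJ"`, `"kcal"`); kilocalories convert
#' at 4.184 kJ/kcal. Columns already canonical pass through unchanged, so the
#' operation is idempotent.
#'
#' @param products product tibble (or any data frame with nutrient columns).
#' @param unit_spec named list/character vector, column -> unit token.
#' @return the table with converted columns.
#' @export
#' @examples
#' p <- tibble::tibble(sodium_mg = 0.4, energy_kJ = 100)
#' normalize_units(p, list(sodium_mg = "g", energy_kJ = "kcal"))
normalize_units <- function(products, unit_spec) {
  canonical <- function(col) {
    if (col == "sodium_mg") "mg" else if (col == "energy_kJ") "kJ" else "g"
  }
  for (col in names(unit_spec)) {
    if (is.null(products[[col]])) next
    unit <- as.character(unit_spec[[col]])
    target <- canonical(col)
    factor <- if (unit == target) {
      1
    } else if (unit == "kcal" && target == "kJ") {
      KJ_PER_KCAL
    } else if (unit == "g" && target == "mg") {
      1000
    } else if (unit == "mg" && target == "g") {
      1 / 1000
    } else {
      abort(paste0("Unknown unit \"", unit, "\" for column `", col,
                   "` (canonical unit: ", target, ")."))
    }
    products[[col]] <- products[[col]] * factor
  }
  products
}

#' Prefer one declaration basis per product
#'
#' Profiling applies to the as-consumed declaration when a product carries
#' one (e.g. concentrates that are reconstituted), falling back to the
#' as-packaged declaration otherwise.
#'
#' @param products product tibble possibly holding both bases per product.
#' @param prefer basis to prefer when both are present.
#' @return one row per `product_id`.
#' @export
prefer_basis <- function(products, prefer = "as_consumed") {
  if (is.null(products[["basis"]])) return(products)
  products |>
    dplyr::mutate(.pref = .data$basis == prefer) |>
    dplyr::arrange(dplyr::desc(.data$.pref)) |>
    dplyr::distinct(.data$product_id, .keep_all = TRUE) |>
    dplyr::select(-".pref")
}
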