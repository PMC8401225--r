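# Threshold-model classification ---------------------------------------------

resolve_flag <- function(products, col, default) {
  v <- products[[col]]
  if (is.null(v)) v <- rep(NA, nrow(products))
  out <- as.logical(v)
  assumed <- is.na(out)
  out[assumed] <- default
  list(value = out, assumed = assumed)
}

cutpoint_for <- function(thresholds, form, nutrient) {
  tab <- ifelse(form == "liquid", "liquids", "solids")
  vapply(seq_along(form), function(i) {
    cp <- thresholds[[tab[i]]][[nutrient]]
    if (is.null(cp)) NA_real_ else cp
  }, numeric(1))
}

flag_value <- function(value, cutpoint, qualified, comparison, missing_excessive) {
  over <- if (comparison == "ge") {
    !is.na(value) & value >= cutpoint - sqrt(.Machine$double.eps)
  } else {
    exceeds(value, cutpoint)
  }
  miss <- is.na(value)
  (over | (miss & missing_excessive)) & qualified
}

threshold_classify <- function(products, thresholds, model, nutrients,
                               qualified, missing_excessive, nss_flag = NULL) {
  n <- nrow(products)
  value_col <- c(sugar = "total_sugar_g", sodium = "sodium_mg",
                 sat_fat = "sat_fat_g", energy = "energy_kJ")
  cp_name <- c(sugar = "total_sugar_g", sodium = "sodium_mg",
               sat_fat = "sat_fat_g", energy = "energy_kJ")
  detail <- lapply(nutrients, function(nu) {
    value <- products[[value_col[[nu]]]] %||% rep(NA_real_, n)
    cp <- cutpoint_for(thresholds, products$form, cp_name[[nu]])
    q <- qualified[[nu]]
    tibble::tibble(
      product_id = products$product_id, nutrient = nu,
      value = value, cutpoint = cp, qualified = q, missing = is.na(value),
      flagged = flag_value(value, cp, q, thresholds$comparison, missing_excessive)
    )
  })
  detail <- dplyr::bind_rows(detail)
  if (!is.null(nss_flag)) {
    detail <- dplyr::bind_rows(detail, tibble::tibble(
      product_id = products$product_id, nutrient = "nss",
      value = NA_real_, cutpoint = NA_real_, qualified = TRUE,
      missing = is.na(nss_flag), flagged = nss_flag
    ))
  }
  wide <- detail |>
    dplyr::select("product_id", "nutrient", "flagged") |>
    tidyr::pivot_wider(names_from = "nutrient", values_from = "flagged",
                       names_prefix = "flag_")
  wide <- wide[match(products$product_id, wide$product_id), ]
  flag_cols <- grep("^flag_", names(wide), value = TRUE)
  n_flags <- rowSums(as.matrix(wide[flag_cols]), na.rm = TRUE)
  res <- tibble::tibble(
    product_id = products$product_id,
    category = products$category,
    form = products$form,
    model = model
  )
  res <- dplyr::bind_cols(res, wide[flag_cols])
  res$n_flags <- as.integer(n_flags)
  res$compliant <- n_flags == 0
  res$detail <- (detail |>
    tidyr::nest(.by = "product_id", .key = "d"))$d[
      match(products$product_id, unique(detail$product_id))]
  res
}

#' Classify products under the Chile Warning Octagon 2019 model
#'
#' Flags energy, total sugar, sodium and saturated fat strictly above their
#' form-specific limits; a product is compliant iff it exceeds none of them.
#' Following the Chilean qualifier, the sugar limit is applied only to
#' products containing added sugar, salt or saturated fat (columns
#' `contains_added_sugar` / `contains_added_sodium` / `contains_added_sat_fat`
#' when present; unknown flags default to qualified).
#'
#' @param products validated product tibble.
#' @param thresholds threshold set; defaults to [thresholds_cwo2019()].
#' @param missing how to treat a missing evaluated nutrient value:
#'   `"error"` (default — the caller must choose a policy), `"excessive"`
#'   (missing counts as exceeding) or `"permissive"` (missing never flags).
#' @return a result tibble with one row per product: per-nutrient `flag_*`
#'   columns, `n_flags`, `compliant`, and a `detail` list-column of
#'   per-nutrient value/cut-point/qualifier records.
#' @export
classify_cwo <- function(products, thresholds = thresholds_cwo2019(),
                         missing = c("error", "excessive", "permissive")) {
  missing <- match.arg(missing)
  stopifnot(inherits(thresholds, "npm_thresholds"))
  products <- prefer_basis(validate_products(products))
  nutrients <- c("sugar", "sodium", "sat_fat",
                 if (thresholds$includes_energy) "energy")
  eval_cols <- c("total_sugar_g", "sodium_mg", "sat_fat_g",
                 if (thresholds$includes_energy) "energy_kJ")
  any_missing <- vapply(eval_cols, function(cl) {
    anyNA(products[[cl]] %||% NA_real_)
  }, logical(1))
  if (missing == "error" && any(any_missing)) {
    abort(paste0(
      "Missing values in evaluated nutrient(s): ",
      paste(eval_cols[any_missing], collapse = ", "),
      ". Choose a policy via `missing = \"excessive\"` (missing counts as ",
      "exceeding) or `missing = \"permissive\"` (missing never flags)."
    ))
  }
  added_any <- resolve_flag(products, "contains_added_sugar", TRUE)$value |
    resolve_flag(products, "contains_added_sodium", FALSE)$value |
    resolve_flag(products, "contains_added_sat_fat", FALSE)$value
  qualified <- list(
    sugar = added_any,
    sodium = rep(TRUE, nrow(products)),
    sat_fat = rep(TRUE, nrow(products)),
    energy = rep(TRUE, nrow(products))
  )
  threshold_classify(products, thresholds, model = "cwo2019",
                     nutrients = nutrients, qualified = qualified,
                     missing_excessive = (missing == "excessive"))
}

#' Classify products under the proposed SA restrictive NPM
#'
#' Applies the across-the-board cut-points with qualifying criteria: sodium
#' is evaluated only for products containing added sodium, total sugar only
#' for products containing a free-sugar source, saturated fat only for
#' products containing added saturated fat; any non-sugar-sweetener content
#' flags regardless of amount. An unknown qualifying flag resolves to
#' qualified (conservative toward flagging), and a missing nutrient value for
#' a qualified nutrient is assessed as excessive by default. The as-consumed
#' declaration is used when a product carries one.
#'
#' @param products validated product tibble; qualifier columns
#'   `contains_free_sugar_source`, `contains_added_sodium`,
#'   `contains_added_sat_fat`, `contains_nss` are honoured when present. A
#'   missing `contains_nss` is derived from `ingredients_text` via
#'   [detect_nss()] when text is available.
#' @param thresholds threshold set; defaults to [thresholds_sa_proposed()].
#' @param nss_terms sweetener term list used when NSS status must be derived.
#' @return a result tibble as in [classify_cwo()], with an additional
#'   `flag_nss` column.
#' @export
classify_sa_proposed <- function(products,
                                 thresholds = thresholds_sa_proposed(),
                                 nss_terms = default_nss_terms()) {
  stopifnot(inherits(thresholds, "npm_thresholds"))
  products <- prefer_basis(validate_products(products))
  qualified <- list(
    sugar = resolve_flag(products, "contains_free_sugar_source", TRUE)$value,
    sodium = resolve_flag(products, "contains_added_sodium", TRUE)$value,
    sat_fat = resolve_flag(products, "contains_added_sat_fat", TRUE)$value
  )
  nss <- as.logical(products[["contains_nss"]] %||% rep(NA, nrow(products)))
  if (anyNA(nss) && !is.null(products[["ingredients_text"]])) {
    todo <- which(is.na(nss) & !is.na(products[["ingredients_text"]]))
    if (length(todo)) {
      nss[todo] <- vapply(products[["ingredients_text"]][todo], function(tx) {
        isTRUE(detect_nss(tx, nss_terms)$contains_nss)
      }, logical(1), USE.NAMES = FALSE)
    }
  }
  # unknown NSS status resolves to qualified/flagged, consistent with the
  # missing-information-defaults-to-excessive stance
  nss[is.na(nss)] <- TRUE
  threshold_classify(products, thresholds, model = "sa_proposed",
                     nutrients = c("sugar", "sodium", "sat_fat"),
                     qualified = qualified, missing_excessive = TRUE,
                     nss_flag = nss)
}
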