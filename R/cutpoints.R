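# Whole-food cut-point context -----------------------------------------------
#
# Candidate cut-points are sanity-checked against a whole/unprocessed-food
# extract of a food composition table (FCT): a sensible restrictive cut-point
# should spare natural foods. Which foods count as whole/unprocessed is an
# upstream editorial decision carried in the extract's inclusion flag, not
# computed here.

#' Read a food-composition-table extract
#'
#' Delimited text with columns `food`, `group`, the per-100 g as-consumed
#' nutrient columns (`energy_kJ`, `total_sugar_g`, `sat_fat_g`, `sodium_mg`,
#' ...), and a logical `included` flag marking the whole/unprocessed list.
#'
#' @param path file path.
#' @param delim delimiter; `NULL` auto-detects from the extension as in
#'   [read_products()].
#' @return a tibble.
#' @export
read_fct <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("FCT file not found: ", path))
  delim <- delim %||% (if (grepl("\\.tsv$", path)) "\t" else ",")
  fct <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                           progress = FALSE, show_col_types = FALSE)
  if (is.null(fct[["included"]])) fct[["included"]] <- TRUE
  fct[["included"]] <- as.logical(fct[["included"]])
  fct
}

#' Distribution summary of a nutrient across whole foods
#'
#' Order statistics (empirical quantiles, type 1 — actual order statistics,
#' no interpolation) of one nutrient over the included FCT entries.
#'
#' @param entries FCT tibble (see [read_fct()]); only rows with
#'   `included = TRUE` and a non-missing value contribute.
#' @param nutrient column name, e.g. `"sodium_mg"`.
#' @param probs percentile levels; default 50/90/95/99.
#' @return a tibble with `statistic` (`min`, `p50`, ..., `max`) and `value`.
#' @export
distribution_summary <- function(entries, nutrient,
                                 probs = c(0.5, 0.9, 0.95, 0.99)) {
  v <- entries[[nutrient]]
  if (is.null(v)) abort(paste0("No column `", nutrient, "` in FCT extract."))
  v <- v[isTRUE_vec(entries[["included"]]) & !is.na(v)]
  if (!length(v)) abort(paste0("No included entries with `", nutrient, "` present."))
  q <- quantile(v, probs = probs, type = 1, names = FALSE)
  tibble::tibble(
    statistic = c("min", paste0("p", round(100 * probs)), "max"),
    value = c(min(v), q, max(v))
  )
}

#' Share of whole foods a threshold set would flag
#'
#' For each nutrient with a cut-point, the fraction of included whole foods
#' strictly exceeding it — the sanity check that restrictive cut-points
#' spare natural, unprocessed foods.
#'
#' @param entries FCT tibble; values are per 100 g, so the solid cut-points
#'   apply.
#' @param thresholds an `npm_thresholds` object.
#' @return a tibble with `nutrient`, `cutpoint`, `n`, `n_flagged`, `rate`.
#' @export
flag_rate_under_cutpoints <- function(entries, thresholds) {
  stopifnot(inherits(thresholds, "npm_thresholds"))
  included <- entries[isTRUE_vec(entries[["included"]]), , drop = FALSE]
  cps <- thresholds$solids
  rows <- purrr::imap(as.list(cps), function(cp, nutrient) {
    v <- included[[nutrient]]
    if (is.null(v)) return(NULL)
    v <- v[!is.na(v)]
    tibble::tibble(
      nutrient = nutrient, cutpoint = cp, n = length(v),
      n_flagged = sum(exceeds(v, cp)),
      rate = if (length(v)) sum(exceeds(v, cp)) / length(v) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}
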