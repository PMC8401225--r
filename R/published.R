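# Published 2018 SA supply summaries ------------------------------------------
#
# The 2018 SA packaged-food survey dataset itself is not redistributable, but
# its published category-level summaries are, and they parameterise the
# synthetic generator and anchor desk-scale recomputations. Two extracts
# ship with the package:
#   - category means, counts and NSS prevalence per sub-category, with the
#     published rollup rows carried verbatim (the beverage rollup row in the
#     source is not exactly the pooled mean of its category rows, so rollups
#     are inputs here, not recomputed);
#   - regulated counts per category under the CWO 2019 criteria.

#' Published category-level summary of the 2018 SA packaged-food supply
#'
#' @return a tibble with `level`, `category`, `n`, `mean_*` nutrient columns,
#'   `nss_count`, `nss_pct`.
#' @export
sa_category_summary <- function() {
  path <- system.file("extdata", "sa_category_summary_2018.csv",
                      package = "foodnpm", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Published CWO 2019 regulated counts for the 2018 SA supply
#'
#' @return a tibble with `level`, `category`, `n`, `regulated_overall`,
#'   `regulated_sugar`, `regulated_sodium`, `regulated_sat_fat`,
#'   `regulated_energy`, `regulated_energy_only`.
#' @export
sa_regulated_counts <- function() {
  path <- system.file("extdata", "sa_cwo_regulated_2018.csv",
                      package = "foodnpm", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
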