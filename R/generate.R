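# Synthetic supply generator --------------------------------------------------
#
# Generates packaged-food supplies with the category structure and
# statistical profile of the published 2018 SA summaries, so the whole
# classification pipeline is exercisable without the proprietary survey
# data. Nutrient amounts are right-skewed and non-negative, so each is drawn
# log-normally, parameterised to hit the configured mean and coefficient of
# variation; saturated and trans fat are drawn as beta-distributed fractions
# of total fat so the panel invariants hold by construction. Product-level
# correlations of the real supply are not emulated.

#' Build a generator configuration
#'
#' @param categories tibble with one row per category: `category`, `n`, the
#'   `mean_*` nutrient columns (as in [sa_category_summary()]) and `nss_prob`.
#' @param seed integer seed; mandatory for any stochastic draw.
#' @param cv coefficient of variation shared by all nutrient draws (the
#'   published summaries carry only means; 0.6 is a modelling choice for
#'   right-skewed nutrient content, not a published value).
#' @param free_sugar_rules category rules used to derive free from total
#'   sugar; defaults to the ratio of configured free to total sugar means.
#' @return a `generator_config` list.
#' @export
generator_config <- function(categories, seed, cv = 0.6,
                             free_sugar_rules = NULL) {
  categories <- tibble::as_tibble(categories)
  if (missing(seed) || is.null(seed)) abort("A `seed` is mandatory.")
  if (is.null(categories$category) || is.null(categories$n)) {
    abort("`categories` needs `category` and `n` columns.")
  }
  if (any(categories$n < 0)) abort("Category sizes must be >= 0.")
  if (!is.null(categories$nss_prob) &&
      any(categories$nss_prob < 0 | categories$nss_prob > 1)) {
    abort("`nss_prob` must lie in [0, 1].")
  }
  mean_cols <- grep("^mean_", names(categories), value = TRUE)
  if (any(as.matrix(categories[mean_cols]) < 0, na.rm = TRUE)) {
    abort("Configured means must be >= 0.")
  }
  if (cv < 0) abort("`cv` must be >= 0.")
  structure(
    list(categories = categories, seed = as.integer(seed), cv = cv,
         free_sugar_rules = free_sugar_rules),
    class = "generator_config"
  )
}

#' Default generator configuration: the 2018 SA supply profile
#'
#' Category sizes, nutrient means and NSS prevalences are taken from the
#' published category summary; the dispersion (CV 0.6) is a modelling
#' choice.
#'
#' @param seed integer seed.
#' @param n_scale optional multiplier on the published category sizes (e.g.
#'   `0.1` for a ten-fold smaller supply); sizes are rounded and kept >= 1.
#' @inheritParams generator_config
#' @return a `generator_config`.
#' @export
default_generator_config <- function(seed, n_scale = 1, cv = 0.6) {
  summ <- sa_category_summary()
  cats <- summ[summ$level == "category", ]
  cats[["nss_prob"]] <- cats$nss_count / cats$n
  if (n_scale != 1) cats$n <- pmax(1L, as.integer(round(cats$n * n_scale)))
  generator_config(
    cats[, c("category", "n", grep("^mean_", names(cats), value = TRUE),
             "nss_prob")],
    seed = seed, cv = cv
  )
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (is.na(mean)) return(rep(NA_real_, n))
  if (mean == 0) {
    if (cv > 0) warn("Mean 0 with CV > 0: degenerate point mass at 0.")
    return(rep(0, n))
  }
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

GENERIC_INGREDIENTS <- list(
  solid = "wheat flour, vegetable oil, salt",
  liquid = "water, flavouring, citric acid"
)

#' Generate a synthetic packaged-food supply
#'
#' Fully reproducible given the config's seed. Nutrient panels satisfy all
#' product-table invariants by construction; NSS-containing products get a
#' matching sweetener token synthesised into their ingredient text and a
#' `contains_nss` flag.
#'
#' @param config a `generator_config`; see [default_generator_config()].
#' @param taxonomy category taxonomy.
#' @param nss_terms term list used to pick sweetener tokens.
#' @return a validated product tibble.
#' @export
#' @examples
#' supply <- generate_supply(default_generator_config(seed = 1, n_scale = 0.02))
#' nrow(supply)
generate_supply <- function(config, taxonomy = default_taxonomy(),
                            nss_terms = default_nss_terms()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  cats <- config$categories
  cv <- config$cv
  sweetener_pool <- unique(nss_terms$canonical)
  out <- vector("list", nrow(cats))
  for (i in seq_len(nrow(cats))) {
    n <- cats$n[i]
    if (n == 0) next
    cat_name <- cats$category[i]
    is_bev <- taxonomy_lookup(taxonomy, cat_name, "is_beverage")
    g <- function(col) {
      m <- cats[[paste0("mean_", col)]]
      if (is.null(m)) rep(NA_real_, n) else rlnorm_mean_cv(n, m[i], cv)
    }
    energy <- g("energy_kJ")
    sugar <- g("total_sugar_g")
    total_fat <- g("total_fat_g")
    sodium <- g("sodium_mg")
    # saturated / trans fat as bounded fractions of total fat, so the
    # panel invariants hold by construction while means stay on target
    frac_of_fat <- function(col) {
      m_part <- cats[[paste0("mean_", col)]]
      m_fat <- cats[["mean_total_fat_g"]]
      if (is.null(m_part) || is.null(m_fat) || is.na(m_part[i])) {
        return(rep(NA_real_, n))
      }
      if (is.na(m_fat[i]) || m_fat[i] == 0) return(rep(0, n))
      r <- min(1, m_part[i] / m_fat[i])
      if (r == 0) return(rep(0, n))
      if (r == 1) return(total_fat)
      total_fat * rbeta(n, r * 5, (1 - r) * 5)
    }
    sat_fat <- frac_of_fat("sat_fat_g")
    trans_fat <- frac_of_fat("trans_fat_g")
    # free sugar as a fixed category-level fraction of total sugar
    f_ratio <- {
      mt <- cats[["mean_total_sugar_g"]]; mf <- cats[["mean_free_sugar_g"]]
      if (is.null(mf) || is.null(mt) || is.na(mf[i]) || is.na(mt[i]) ||
          mt[i] == 0) 1 else min(1, mf[i] / mt[i])
    }
    free_sugar <- sugar * f_ratio
    p_nss <- if (is.null(cats[["nss_prob"]])) 0 else cats[["nss_prob"]][i]
    has_nss <- rbinom(n, 1, p_nss) == 1
    base_text <- if (is_bev) GENERIC_INGREDIENTS$liquid else GENERIC_INGREDIENTS$solid
    sweetener <- sample(sweetener_pool, n, replace = TRUE)
    ingredients <- ifelse(has_nss, paste0(base_text, ", ", sweetener), base_text)

    out[[i]] <- tibble::tibble(
      product_id = sprintf("%s-%04d", gsub("[^a-z0-9]+", "_", tolower(cat_name)),
                           seq_len(n)),
      category = cat_name,
      form = if (is_bev) "liquid" else "solid",
      basis = "as_packaged",
      nip_present = TRUE,
      energy_kJ = energy,
      total_sugar_g = sugar,
      free_sugar_g = free_sugar,
      total_fat_g = total_fat,
      sat_fat_g = sat_fat,
      trans_fat_g = trans_fat,
      sodium_mg = sodium,
      ingredients_text = ingredients,
      contains_nss = has_nss
    )
  }
  supply <- dplyr::bind_rows(out)
  validate_products(supply, taxonomy = taxonomy)
}
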