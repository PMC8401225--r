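# FVNL percentage estimation --------------------------------------------------
#
# Fruit/vegetable/nut/legume content is rarely declared on SA panels, so the
# scored model needs an estimate. The survey work used manual dietitian
# judgement over the ingredient list (order of ingredients, concentrated vs
# whole form, FVNL vs non-FVNL counts); this module emulates that judgement
# with a deterministic banded heuristic driven by an editable rule config.

#' Default FVNL estimation rules
#'
#' @return a list with `bands` (allowed percentages), `fvnl_terms`,
#'   `concentrated_terms`, `negligible_terms` and demotion settings.
#' @export
default_fvnl_rules <- function() {
  read_pkg_yaml("fvnl_rules.yaml")
}

split_ingredients <- function(text) {
  parts <- strsplit(tolower(text), "[,;]\\s*")[[1]]
  parts <- gsub("\\(.*?\\)", " ", parts)
  parts <- trimws(gsub("\\s+", " ", parts))
  parts[nzchar(parts)]
}

matches_any_term <- function(token, terms) {
  any(vapply(terms, function(tm) grepl(paste0("\\b", tm, "\\b"), token),
             logical(1)))
}

#' Estimate FVNL percentage from ingredient text
#'
#' Deterministic banded estimate: categories that cannot contain FVNLs score
#' 0; otherwise negligible ingredients (water, salt, preservatives, ...) are
#' dropped, the rank of the first FVNL ingredient selects a starting band
#' (first ingredient -> top band), and the estimate is demoted one band when
#' the FVNL ingredient is in concentrated form and when FVNL ingredients are
#' a small minority of the list. No FVNL tokens at all scores 0; an eligible
#' category without ingredient text yields `NA` (unknown), which propagates
#' as missing FVNL.
#'
#' @param products product tibble with `category` and `ingredients_text`.
#' @param taxonomy category taxonomy (supplies `fvnl_eligible`).
#' @param rules rule configuration; see [default_fvnl_rules()].
#' @return numeric vector of banded percentages (by default
#'   0/25/50/75/100) or `NA`.
#' @export
#' @examples
#' p <- tibble::tibble(
#'   product_id = "a", category = "legumes",
#'   ingredients_text = "chickpeas, water, salt"
#' )
#' estimate_fvnl_percent(p)
estimate_fvnl_percent <- function(products, taxonomy = default_taxonomy(),
                                  rules = default_fvnl_rules()) {
  eligible <- taxonomy_lookup(taxonomy, products$category, "fvnl_eligible")
  text <- products[["ingredients_text"]] %||% rep(NA_character_, nrow(products))
  bands <- sort(as.numeric(rules$bands))
  demote <- function(band) {
    i <- match(band, bands)
    bands[max(1L, i - 1L)]
  }
  vapply(seq_len(nrow(products)), function(i) {
    if (!eligible[i]) return(0)
    if (is.na(text[i]) || !nzchar(trimws(text[i]))) return(NA_real_)
    tokens <- split_ingredients(text[i])
    tokens <- tokens[!vapply(tokens, matches_any_term, logical(1),
                             terms = rules$negligible_terms)]
    if (!length(tokens)) return(0)
    is_fvnl <- vapply(tokens, matches_any_term, logical(1),
                      terms = rules$fvnl_terms)
    if (!any(is_fvnl)) return(0)
    rank1 <- which(is_fvnl)[1]
    # starting band from the rank of the first FVNL ingredient
    ladder <- rules$rank_bands
    band <- 0
    for (rb in ladder) {
      if (rank1 <= rb$max_rank) { band <- rb$band; break }
    }
    if (band == 0) return(0)
    concentrated <- matches_any_term(tokens[rank1], rules$concentrated_terms)
    if (concentrated) band <- demote(band)
    if (mean(is_fvnl) < rules$minority_share) band <- demote(band)
    band
  }, numeric(1))
}
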