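# Non-sugar-sweetener detection ----------------------------------------------

#' Default non-sugar-sweetener term list
#'
#' Canonical intense sweeteners (aspartame, acesulfame, sucralose, saccharin,
#' cyclamate, steviol glycosides, neotame, advantame, thaumatin,
#' neohesperidin DC) and polyols (sorbitol, mannitol, isomalt, maltitol,
#' lactitol, xylitol, erythritol, polyglycitol), each with synonyms and
#' additive E-number codes. Shipped as versioned YAML so that a
#' survey-specific search-term list can be substituted verbatim.
#'
#' @param path optional YAML path overriding the shipped list.
#' @return a tibble with columns `canonical`, `class`
#'   (`"intense"`/`"polyol"`) and `term` (one row per search term,
#'   lower-case, unique).
#' @export
default_nss_terms <- function(path = NULL) {
  cfg <- if (is.null(path)) read_pkg_yaml("nss_terms.yaml") else yaml::read_yaml(path)
  rows <- purrr::map(cfg$sweeteners, function(sw) {
    tibble::tibble(
      canonical = sw$canonical,
      class = sw$class,
      term = tolower(unique(c(sw$canonical, unlist(sw$synonyms))))
    )
  })
  terms <- dplyr::bind_rows(rows)
  if (anyDuplicated(terms$term)) {
    dup <- terms$term[duplicated(terms$term)]
    abort(paste0("Duplicate NSS term(s): ", paste(unique(dup), collapse = ", ")))
  }
  terms
}

normalize_ingredient_text <- function(text) {
  x <- tolower(text)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Detect non-sugar sweeteners in ingredient text
#'
#' Case-insensitive matching of the term list against punctuation-stripped
#' text with word-boundary guards, so "polysaccharide" never matches
#' saccharin. Multi-word terms match across flexible whitespace.
#'
#' @param text a single ingredient string.
#' @param terms term list tibble; see [default_nss_terms()].
#' @return a list with `matches` (canonical sweetener names, possibly
#'   empty) and `contains_nss` (`TRUE`/`FALSE`, or `NA` when the text is
#'   empty or missing — absence of evidence is not evidence of absence).
#' @export
#' @examples
#' detect_nss("Carbonated water, Aspartame, Acesulfame K")
#' detect_nss("polysaccharide thickener")
detect_nss <- function(text, terms = default_nss_terms()) {
  if (length(text) != 1) abort("`text` must be a single string; use lapply for many.")
  if (is.na(text) || !nzchar(trimws(text))) {
    return(list(matches = character(0), contains_nss = NA))
  }
  norm <- normalize_ingredient_text(text)
  hit <- vapply(terms$term, function(tm) {
    pattern <- paste0("\\b", gsub(" ", "\\\\s+", normalize_ingredient_text(tm)), "\\b")
    grepl(pattern, norm)
  }, logical(1))
  matches <- sort(unique(terms$canonical[hit]))
  list(matches = matches, contains_nss = length(matches) > 0)
}

#' Non-sugar-sweetener prevalence
#'
#' Count and percentage of products containing at least one NSS, overall or
#' per category. Uses a `contains_nss` column when present, otherwise
#' detects from `ingredients_text`.
#'
#' @param products product tibble.
#' @param by optional grouping column (e.g. `"category"`).
#' @param terms term list used when detection is needed.
#' @return a tibble with `n`, `nss_count`, `nss_pct` (1 decimal place,
#'   half-up), plus the grouping column if requested.
#' @export
nss_prevalence <- function(products, by = NULL, terms = default_nss_terms()) {
  if (nrow(products) == 0) abort("Empty product set: prevalence is undefined.")
  flags <- products[["contains_nss"]]
  if (is.null(flags)) {
    if (is.null(products[["ingredients_text"]])) {
      abort("Need a `contains_nss` column or `ingredients_text` to detect from.")
    }
    flags <- vapply(products[["ingredients_text"]], function(tx) {
      isTRUE(detect_nss(tx, terms)$contains_nss)
    }, logical(1), USE.NAMES = FALSE)
  }
  df <- tibble::tibble(.flag = !is.na(flags) & flags)
  if (!is.null(by)) df[[by]] <- products[[by]]
  df |>
    dplyr::group_by(dplyr::across(dplyr::any_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      nss_count = sum(.data$.flag),
      nss_pct = share_pct(sum(.data$.flag), dplyr::n()),
      .groups = "drop"
    )
}
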