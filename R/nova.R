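# NOVA heuristic -------------------------------------------------------------
#
# Processing-level assignment used to characterise the supply. This is a
# transparent, user-configurable marker-list heuristic over the ingredient
# text: any ultra-processed marker assigns group 4, else any processed marker
# assigns group 3, else group 1. Culinary ingredients (group 2) are omitted,
# as packaged-supply summaries conventionally drop them. It is not a
# re-derivation of the full NOVA methodology.

#' Default NOVA marker configuration
#'
#' Group-4 (ultra-processed) markers are ingredients characteristic of
#' industrial formulation: sweeteners, flavourants, emulsifiers, modified
#' starches, protein isolates and the like. Group-3 (processed) markers are
#' culinary additions to whole foods: salt, sugar, oil, vinegar. Unmatched
#' products with ingredient text default to group 1 (unprocessed/minimally
#' processed); `category_defaults` may supply a group for products without
#' ingredient text.
#'
#' @return a list with elements `group4`, `group3`, `category_defaults`.
#' @export
default_nova_markers <- function() {
  read_pkg_yaml("nova_markers.yaml")
}

#' Assign NOVA processing groups from ingredient text
#'
#' @param products product tibble with `ingredients_text` (optional
#'   per product) and `category`.
#' @param markers marker configuration; see [default_nova_markers()].
#' @return integer vector of groups (1, 3 or 4), `NA` where neither
#'   ingredient text nor a category default is available (unclassifiable,
#'   excluded from NOVA summaries).
#' @export
#' @examples
#' p <- tibble::tibble(
#'   product_id = "x", category = "legumes",
#'   ingredients_text = "peas, water, salt"
#' )
#' assign_nova(p)
assign_nova <- function(products, markers = default_nova_markers()) {
  if (!length(markers$group4) || !length(markers$group3)) {
    abort("NOVA marker lists must be non-empty.")
  }
  text <- tolower(products[["ingredients_text"]] %||% rep(NA_character_, nrow(products)))
  match_any <- function(txt, terms) {
    if (is.na(txt)) return(NA)
    any(vapply(terms, function(tm) {
      grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tolower(tm)), "\\b"), txt)
    }, logical(1)))
  }
  g4 <- vapply(text, match_any, logical(1), terms = markers$group4, USE.NAMES = FALSE)
  g3 <- vapply(text, match_any, logical(1), terms = markers$group3, USE.NAMES = FALSE)
  defaults <- markers$category_defaults %||% list()
  out <- integer(nrow(products))
  for (i in seq_len(nrow(products))) {
    if (is.na(text[i])) {
      d <- defaults[[products$category[i]]]
      out[i] <- if (is.null(d)) NA_integer_ else as.integer(d)
    } else if (isTRUE(g4[i])) {
      out[i] <- 4L
    } else if (isTRUE(g3[i])) {
      out[i] <- 3L
    } else {
      out[i] <- 1L
    }
  }
  out
}
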