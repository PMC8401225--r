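# Threshold sets --------------------------------------------------------------

#' Construct a threshold set
#'
#' A threshold set names an NPM's per-form cut-points and comparison
#' semantics. "Exceed" means strictly greater than the cut-point throughout
#' (a product sitting exactly at a limit is compliant); a >=-dialect can be
#' selected with `comparison = "ge"`.
#'
#' @param name model name.
#' @param solids,liquids named numeric vectors/lists of cut-points per 100 g
#'   (solids) or 100 mL (liquids); recognised names: `sodium_mg`,
#'   `total_sugar_g`, `sat_fat_g`, `energy_kJ`.
#' @param includes_energy,includes_nss whether the model evaluates energy /
#'   flags any non-sugar-sweetener content.
#' @param comparison `"gt"` (strict exceed, default) or `"ge"`.
#' @return an object of class `npm_thresholds`.
#' @export
npm_thresholds <- function(name, solids, liquids,
                           includes_energy = FALSE, includes_nss = FALSE,
                           comparison = c("gt", "ge")) {
  comparison <- match.arg(comparison)
  solids <- unlist(solids); liquids <- unlist(liquids)
  if (any(solids <= 0) || any(liquids <= 0)) {
    abort("All cut-points must be positive.")
  }
  shared <- intersect(names(solids), names(liquids))
  if (any(liquids[shared] > solids[shared])) {
    abort("Liquid cut-points must not exceed the corresponding solid cut-points.")
  }
  structure(
    list(name = name, solids = solids, liquids = liquids,
         includes_energy = includes_energy, includes_nss = includes_nss,
         comparison = comparison),
    class = "npm_thresholds"
  )
}

#' @export
print.npm_thresholds <- function(x, ...) {
  cat("<npm_thresholds> ", x$name, "\n", sep = "")
  cat("  solids : ", paste(names(x$solids), x$solids, sep = "=", collapse = ", "), "\n")
  cat("  liquids: ", paste(names(x$liquids), x$liquids, sep = "=", collapse = ", "), "\n")
  cat("  energy evaluated: ", x$includes_energy,
      " | NSS evaluated: ", x$includes_nss,
      " | comparison: ", x$comparison, "\n", sep = "")
  invisible(x)
}

#' Load a threshold set from YAML
#'
#' @param path YAML file with fields `name`, `solids`, `liquids`,
#'   `includes_energy`, `includes_nss`, and optionally `comparison`.
#' @return an `npm_thresholds` object.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  npm_thresholds(
    name = cfg$name, solids = cfg$solids, liquids = cfg$liquids,
    includes_energy = isTRUE(cfg$includes_energy),
    includes_nss = isTRUE(cfg$includes_nss),
    comparison = cfg$comparison %||% "gt"
  )
}

#' Chile Warning Octagon 2019 cut-points
#'
#' Final-phase limits per 100 g (solids) / 100 mL (liquids) for energy, total
#' sugar, saturated fat and sodium. The sugar/fat/sodium limits match the
#' proposed SA set; the energy limits (275 kcal/100 g and 70 kcal/100 mL,
#' converted at 4.184 kJ/kcal) are taken from the Chilean regulation itself
#' and are labelled externally sourced in the shipped config.
#'
#' @return an `npm_thresholds` object.
#' @export
thresholds_cwo2019 <- function() {
  read_thresholds(system.file("extdata", "thresholds_cwo2019.yaml",
                              package = "foodnpm", mustWork = TRUE))
}

#' Proposed SA restrictive NPM cut-points
#'
#' Across-the-board limits adapted from the Chilean approach: solids
#' 400 mg sodium / 10 g total sugar / 4 g saturated fat per 100 g; liquids
#' 100 mg / 5 g / 3 g per 100 mL; any non-sugar-sweetener content flags.
#' Energy is not evaluated.
#'
#' @return an `npm_thresholds` object.
#' @export
thresholds_sa_proposed <- function() {
  read_thresholds(system.file("extdata", "thresholds_sa_proposed.yaml",
                              package = "foodnpm", mustWork = TRUE))
}
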