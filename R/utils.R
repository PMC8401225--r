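#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages here follow the
#' half-up convention used on nutrition panels and in the supply tables, so
#' 53.95 rounds to 54.0, not 53.9.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(53.95, 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage share, rounded half-up
#'
#' @param count numerator count.
#' @param n denominator count; must be positive.
#' @param digits decimal places (default 1, the convention in the supply
#'   summary tables).
#' @return `100 * count / n`, rounded.
#' @export
share_pct <- function(count, n, digits = 1) {
  stopifnot(is.numeric(count), is.numeric(n))
  if (any(n <= 0)) abort("`n` must be positive to compute a percentage share.")
  round_half_up(100 * count / n, digits)
}

# kcal -> kJ conversion factor (thermochemical calorie convention used on
# food labels)
KJ_PER_KCAL <- 4.184

# strict-exceed comparison with a tolerance guard so that values sitting
# exactly at a cut-point (e.g. sodium 400 mg) never flag
exceeds <- function(value, cutpoint) {
  !is.na(value) & !is.na(cutpoint) &
    (value > cutpoint + sqrt(.Machine$double.eps) * pmax(1, abs(cutpoint)))
}

read_pkg_yaml <- function(name) {
  path <- system.file("extdata", name, package = "foodnpm", mustWork = TRUE)
  yaml::read_yaml(path)
}

`%!in%` <- function(x, table) !(x %in% table)
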