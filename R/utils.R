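#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up in magnitude), used for all
#' reported densities and coefficients. `base::round()` rounds half to even,
#' which does not match how the reference tables were rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @examples
#' round_half_up(0.185, 2) # 0.19, where round(0.185, 2) gives 0.18
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

match_resource <- function(resource) {
  match.arg(resource, resource_kinds)
}

match_basis <- function(basis) {
  match.arg(basis, basis_kinds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
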