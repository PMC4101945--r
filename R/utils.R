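#' Round half away from zero
#'
#' Decimal rounding with ties going up (`2.5 -> 3`), the convention used
#' throughout the reporting chain (base `round()` rounds ties to even).  A
#' tiny epsilon absorbs binary representation error so that quantities that
#' are exact halves in rational arithmetic (e.g. `122/40 = 3.05`) round up.
#'
#' @param x numeric vector (nonnegative in all package uses).
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties up.
#' @examples
#' round_half_up(3.05, 1)  # 3.1
#' round_half_up(2.5)      # 3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

abort_config <- function(msg) abort(msg, class = "rheosense_config_error")
abort_validation <- function(msg) abort(msg, class = "rheosense_validation_error")
abort_structure <- function(msg) abort(msg, class = "rheosense_structure_error")

check_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_config(sprintf("`%s` must be a single finite number", name))
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    abort_config(sprintf("`%s` = %g is outside its allowed range", name, x))
  invisible(x)
}

#' Label 4-connected components of a mask
#'
#' Foreground pixels sharing an edge (not just a corner) receive the same
#' positive integer label; background is 0.  Used for ground-truth plant
#' components and for the detector's oracle checks; 4-connectivity avoids
#' diagonal bridges joining plants at the minimum-mapping-unit boundary.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; labels 1..K, background 0.
#' @export
label_components <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask))
    abort_structure("`mask` must be a logical matrix")
  cpp_label4(mask)
}
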