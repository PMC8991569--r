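#' Define a controllable culture factor
#'
#' A factor is a culture variable (a medium component, pH, culture volume,
#' incubation time, ...) screened or optimized over a two- or three-level
#' range. Natural units are mapped onto coded units so that `low`, `center`
#' and `high` correspond to coded -1, 0 and +1.
#'
#' @param name Short label, e.g. `"CaCl2"`.
#' @param low Natural value at coded -1.
#' @param high Natural value at coded +1. Must exceed `low`.
#' @param center Natural value at coded 0. Defaults to the midpoint
#'   `(low + high) / 2` and must lie strictly between `low` and `high`.
#' @param unit Unit string for reporting, e.g. `"g/L"` or `"mL/500 mL"`.
#'
#' @return An object of class `doe_factor`.
#' @examples
#' cacl2 <- designFactor("CaCl2", low = 0.375, high = 1.125, unit = "g/L")
#' codeLevels(cacl2, 1.125)   # +1
#' decodeLevels(cacl2, -1)    # 0.375
#' @export
designFactor <- function(name, low, high, center = (low + high) / 2,
                         unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low); high <- as.numeric(high); center <- as.numeric(center)
  if (!is.finite(low) || !is.finite(high) || !is.finite(center))
    stop("factor '", name, "': levels must be finite numbers")
  if (!(low < high))
    stop("factor '", name, "': 'low' (", low, ") must be < 'high' (", high, ")")
  if (!(low < center && center < high))
    stop("factor '", name, "': 'center' (", center,
         ") must lie strictly between low and high")
  structure(
    list(name = name, unit = unit, low = low, center = center, high = high),
    class = "doe_factor"
  )
}

#' @export
print.doe_factor <- function(x, ...) {
  u <- if (nzchar(x$unit)) paste0(" ", x$unit) else ""
  cat(sprintf("Factor %s: -1[%g] 0[%g] +1[%g]%s\n",
              x$name, x$low, x$center, x$high, u))
  invisible(x)
}

#' Convert natural factor levels to coded units
#'
#' Coded value `(natural - center) / ((high - low) / 2)`; exactly -1, 0 and
#' +1 at the factor's three defining levels. The mapping is affine, so
#' intermediate natural values code to intermediate coded values.
#'
#' @param factor A [designFactor()] object.
#' @param natural Numeric vector of natural-unit values.
#' @return Numeric vector of coded values.
#' @seealso [decodeLevels()] for the inverse.
#' @export
codeLevels <- function(factor, natural) {
  stopifnot(inherits(factor, "doe_factor"))
  half <- (factor$high - factor$low) / 2
  if (half == 0) stop("factor '", factor$name, "' has zero range")
  (as.numeric(natural) - factor$center) / half
}

#' Convert coded factor levels to natural units
#'
#' Inverse of [codeLevels()]: `center + coded * (high - low) / 2`.
#'
#' @param factor A [designFactor()] object.
#' @param coded Numeric vector of coded values.
#' @return Numeric vector of natural-unit values.
#' @export
decodeLevels <- function(factor, coded) {
  stopifnot(inherits(factor, "doe_factor"))
  factor$center + as.numeric(coded) * (factor$high - factor$low) / 2
}
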