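#' Normalise a spectrum to unit area
#'
#' Rescales the intensity so the trapezoidal area under the curve on the
#' native grid equals one; the abscissa is untouched. Intended for
#' comparing band shapes across samples (e.g. infrared spectra) where the
#' overall intensity scale is not meaningful. The area is computed on the
#' signed `y` (no absolute value, no baseline handling); a total area that
#' is zero, negative or non-finite raises a normalisation error.
#'
#' The operation is idempotent and invariant to rescaling of `y`.
#'
#' @param spec A data frame with columns `x` (strictly increasing abscissa:
#'   wavenumber, frequency, ...) and `y` (intensity).
#' @return A tibble with the same `x` and rescaled `y`.
#' @export
#' @examples
#' area_normalize(tibble::tibble(x = c(0, 10), y = c(2, 2)))  # y = 0.05
area_normalize <- function(spec) {
  if (!is.data.frame(spec) || !all(c("x", "y") %in% names(spec)))
    abort_class("`spec` must have columns `x` and `y`", "thztds_input_error")
  if (nrow(spec) < 2 || any(!is.finite(spec$x)) || any(!is.finite(spec$y)))
    abort_class("`spec` needs >= 2 finite points", "thztds_input_error")
  if (any(diff(spec$x) <= 0))
    abort_class("`x` must be strictly increasing", "thztds_input_error")
  area <- pracma::trapz(spec$x, spec$y)
  if (!is.finite(area) || area <= 0)
    abort_class(sprintf("total area under the curve is %.3g; cannot normalise",
                        area), "thztds_normalization_error")
  tibble(x = spec$x, y = spec$y / area)
}
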