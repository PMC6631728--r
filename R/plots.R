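#' Plot a waveform
#'
#' @param object A `thz_waveform`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thz_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ps)", y = "Field amplitude (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a spectral magnitude
#'
#' @param object A `thz_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thz_spectrum <- function(object, ...) {
  df <- tibble(frequency = object$frequency, magnitude = Mod(object$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$magnitude)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (THz)", y = "|E| (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot extracted optical constants
#'
#' Two stacked panels: refractive index and absorption coefficient across
#' the usable band.
#'
#' @param object A `thz_optical_constants`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thz_optical_constants <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble(frequency = object$frequency, `n` = object$n,
           `alpha (cm^-1)` = object$alpha),
    -"frequency", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Frequency (THz)", y = NULL) +
    ggplot2::theme_minimal()
}
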