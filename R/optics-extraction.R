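# Tukey-style window: raised-cosine ramps over `taper_fraction` of each end
raised_cosine_taper <- function(n, taper_fraction) {
  w <- rep(1, n)
  m <- floor(taper_fraction * n)
  if (m > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / m))
    w[seq_len(m)] <- ramp
    w[n - seq_len(m) + 1] <- ramp
  }
  w
}

#' Transform a waveform to the frequency domain
#'
#' Subtracts the mean (DC offset), applies a raised-cosine (Tukey) taper
#' over a fraction of each end of the trace, zero-pads, and takes the
#' discrete Fourier transform. Only the non-negative-frequency half is
#' returned; the frequency resolution is `1/(pad_factor * time_span)`.
#'
#' The transform convention is the plain unnormalised DFT
#' \eqn{X_k = \sum_n x_n e^{-2\pi i k n / N}}, under which a time delay
#' \eqn{\Delta t} multiplies the spectrum by \eqn{e^{-i 2\pi\nu \Delta t}}.
#'
#' @param wave A `thz_waveform` tibble (columns `time` in ps, `amplitude`).
#' @param taper_fraction Fraction of each end tapered, in `[0, 0.5)`.
#' @param pad_factor Integer zero-padding factor, `>= 1`.
#' @return A `thz_spectrum` tibble with columns `frequency` (THz) and
#'   `value` (complex amplitude).
#' @export
to_frequency_domain <- function(wave, taper_fraction = 0.05, pad_factor = 2) {
  validate_waveform(wave)
  if (taper_fraction < 0 || taper_fraction >= 0.5)
    abort_config("taper_fraction", "must be in [0, 0.5)")
  pad_factor <- as.integer(pad_factor)
  if (is.na(pad_factor) || pad_factor < 1)
    abort_config("pad_factor", "must be an integer >= 1")

  x <- wave$amplitude - mean(wave$amplitude)
  n <- length(x)
  if (taper_fraction > 0) x <- x * raised_cosine_taper(n, taper_fraction)
  npad <- pad_factor * n
  X <- fft(c(x, rep(0, npad - n)))
  dt <- wave$time[2] - wave$time[1]
  kmax <- npad %/% 2
  out <- tibble(frequency = (0:kmax) / (npad * dt), value = X[1:(kmax + 1)])
  attr(out, "sample_interval") <- dt
  attr(out, "n_time") <- n
  attr(out, "n_fft") <- npad
  class(out) <- c("thz_spectrum", class(out))
  out
}

#' Gate out the Fabry-Perot echo in the time domain
#'
#' Internal reflection off the two faces of the sample slab produces a
#' delayed replica of the main pulse `2 n d / c` after it, which shows up
#' as an oscillation of the spectral amplitude unless removed. This gate
#' keeps the waveform up to the predicted echo arrival, rolling off with a
#' half raised cosine that ends exactly at the echo time, and zeros
#' everything after.
#'
#' @param wave A `thz_waveform`.
#' @param geometry A [slab_geometry()]; supplies the thickness `d`.
#' @param n_estimate Rough refractive index of the sample (`> 1`) used to
#'   predict the echo delay; 10% accuracy is ample.
#' @param rolloff_ps Length of the half-raised-cosine roll-off, ps. It is
#'   shortened automatically if the echo follows the main peak by less
#'   than this.
#' @return A `thz_waveform` on the same grid, zero after the gate.
#' @export
gate_reflections <- function(wave, geometry, n_estimate, rolloff_ps = 2) {
  validate_waveform(wave)
  validate_geometry(geometry)
  if (!is.finite(n_estimate) || n_estimate <= 1)
    abort_config("n_estimate", "must be > 1")
  t <- wave$time
  t_peak <- t[which.max(abs(wave$amplitude))]
  echo_delay <- 2 * n_estimate * geometry$thickness_um / C_UM_PS
  t_echo <- t_peak + echo_delay
  if (t_echo <= t_peak)
    abort_class("predicted echo does not trail the main peak",
                "thztds_geometry_error")
  roll <- min(rolloff_ps, echo_delay / 2)
  w <- rep(1, length(t))
  ramp <- t > t_echo - roll & t <= t_echo
  w[ramp] <- 0.5 * (1 + cos(pi * (t[ramp] - (t_echo - roll)) / roll))
  w[t > t_echo] <- 0
  new_waveform(t, wave$amplitude * w, label = attr(wave, "label"),
               metadata = c(attr(wave, "metadata"),
                            list(gate_ps = t_echo, gate_rolloff_ps = roll)))
}

#' Anchor an unwrapped phase to zero at zero frequency
#'
#' Phase unwrapping leaves an arbitrary common offset of `2*pi*k`. The
#' physically delayed phase of a transmission measurement must extrapolate
#' to zero at zero frequency, so the low-frequency portion of the unwrapped
#' phase is fitted with a straight line and the integer multiple of `2*pi`
#' closest to its intercept is subtracted from the whole curve.
#'
#' @param frequency Frequency grid, THz.
#' @param phase Unwrapped phase, radians.
#' @param anchor_band Band (THz) used for the linear extrapolation.
#' @return The anchored phase vector.
#' @export
anchor_phase <- function(frequency, phase, anchor_band = c(0.2, 0.5)) {
  sel <- frequency >= anchor_band[1] & frequency <= anchor_band[2] &
    is.finite(phase)
  if (sum(sel) < 2)
    abort_class("too few finite phase points inside the anchor band",
                "thztds_band_error")
  fit <- lm(phase[sel] ~ frequency[sel])
  k <- round(unname(coef(fit)[1]) / (2 * pi))
  phase - 2 * pi * k
}

# build the (frequency, value, phase_unwrapped) tibble from complex values
new_transfer <- function(frequency, value, anchor_band, usable_band) {
  phase <- rep(NA_real_, length(value))
  finite <- is.finite(Re(value)) & is.finite(Im(value)) & Mod(value) > 0
  phase[finite] <- signal::unwrap(Arg(value[finite]))
  phase <- anchor_phase(frequency, phase, anchor_band)
  out <- tibble(frequency = frequency, value = value, phase_unwrapped = phase)
  attr(out, "usable_band") <- usable_band
  class(out) <- c("thz_transfer", class(out))
  out
}

#' Construct a transfer function from complex values
#'
#' Convenience constructor for an analytically known `H(nu)` (e.g. when
#' validating the inversion against a closed form): unwraps and anchors the
#' phase exactly as [transfer_function()] does.
#'
#' @param frequency Strictly increasing frequency grid, THz (zero excluded).
#' @param value Complex transfer-function values.
#' @param anchor_band Band used by [anchor_phase()].
#' @param usable_band Optional band (THz) within which extraction is
#'   trusted; defaults to the grid range clipped to 0.2--2.2 THz.
#' @return A `thz_transfer` tibble.
#' @export
transfer_from_spectrum <- function(frequency, value,
                                   anchor_band = c(0.2, 0.5),
                                   usable_band = NULL) {
  if (any(frequency <= 0) || any(diff(frequency) <= 0))
    abort_class("`frequency` must be strictly increasing and positive",
                "thztds_input_error")
  usable_band <- usable_band %||%
    c(max(min(frequency), INSTRUMENT_BAND[1]),
      min(max(frequency), INSTRUMENT_BAND[2]))
  new_transfer(frequency, value, anchor_band, usable_band)
}

#' Complex transfer function of a sample/reference spectrum pair
#'
#' Pointwise complex ratio `H = E_sam / E_ref` on a shared frequency grid,
#' with the phase unwrapped along frequency and anchored so that its
#' low-frequency linear extrapolation passes through zero at zero frequency
#' (see [anchor_phase()]). The zero-frequency bin is dropped (the DC term
#' was removed before transforming and carries no information).
#'
#' The usable band -- where the reference has enough signal for the
#' inversion to be trusted -- is recorded as an attribute: bins where the
#' reference magnitude is at least 1% of its peak, clipped to the
#' instrument band 0.2--2.2 THz.
#'
#' @param sample_spec,ref_spec `thz_spectrum` tibbles on identical grids.
#' @param anchor_band Band (THz) for phase anchoring.
#' @return A `thz_transfer` tibble with columns `frequency`, `value`,
#'   `phase_unwrapped` and attribute `usable_band`.
#' @export
transfer_function <- function(sample_spec, ref_spec,
                              anchor_band = c(0.2, 0.5)) {
  if (nrow(sample_spec) != nrow(ref_spec) ||
      max(abs(sample_spec$frequency - ref_spec$frequency)) > 1e-12)
    abort_class("sample and reference spectra must share one frequency grid",
                "thztds_input_error")
  rmag <- Mod(ref_spec$value)
  if (max(rmag) < 1e-12)
    abort_class("reference spectrum is below the machine-noise floor",
                "thztds_degenerate_reference_error")
  keep <- ref_spec$frequency > 0
  f <- ref_spec$frequency[keep]
  rv <- ref_spec$value[keep]
  sv <- sample_spec$value[keep]
  H <- sv / rv
  H[Mod(rv) < 1e-12 * max(rmag)] <- NA_complex_
  band <- magnitude_band(f, Mod(rv))
  usable <- c(max(band[1], INSTRUMENT_BAND[1]), min(band[2], INSTRUMENT_BAND[2]))
  new_transfer(f, H, anchor_band, usable)
}

#' Invert a transfer function into optical constants
#'
#' Analytic thick-sample inversion of the slab transfer function. In
#' free-standing mode
#' \deqn{n(\nu) = 1 + \frac{c\,(-\varphi(\nu))}{2\pi\nu d}, \qquad
#'       \alpha(\nu) = -\frac{2}{d}\,
#'         \ln\!\left[|H(\nu)|\,\frac{(n+1)^2}{4n}\right],}
#' with \eqn{\varphi} the anchored unwrapped phase and `d` the thickness.
#' In quartz-windowed mode the leading 1 becomes the window index `n_q` and
#' the Fresnel factor becomes \eqn{4 n n_q/(n+n_q)^2}. Results are reported
#' only inside the usable band; `alpha` is in cm^-1.
#'
#' @param H A `thz_transfer` (from [transfer_function()] or
#'   [transfer_from_spectrum()]).
#' @param geometry A [slab_geometry()].
#' @param band Optional band (THz) overriding the usable band stored on `H`.
#' @return A `thz_optical_constants` tibble with columns `frequency`, `n`,
#'   `alpha` and attribute `usable_band`.
#' @export
extract_optical_constants <- function(H, geometry, band = NULL) {
  validate_geometry(geometry)
  if (!all(c("frequency", "value", "phase_unwrapped") %in% names(H)))
    abort_class("`H` must have columns frequency, value, phase_unwrapped",
                "thztds_input_error")
  usable <- band %||% attr(H, "usable_band") %||% INSTRUMENT_BAND
  keep <- H$frequency > 0 & H$frequency >= usable[1] &
    H$frequency <= usable[2] & is.finite(H$phase_unwrapped)
  f <- H$frequency[keep]
  phi <- H$phase_unwrapped[keep]
  mag <- Mod(H$value[keep])

  nref <- ref_index(geometry)
  d_m <- geometry$thickness_um * 1e-6
  nu_hz <- f * 1e12
  n_hat <- nref + C_M_S * (-phi) / (2 * pi * nu_hz * d_m)
  fresnel <- 4 * n_hat * nref / (n_hat + nref)^2
  alpha_m <- -(2 / d_m) * log(mag / fresnel)
  out <- tibble(frequency = f, n = n_hat, alpha = alpha_m / 100)
  attr(out, "usable_band") <- usable
  attr(out, "geometry") <- unclass(geometry)
  class(out) <- c("thz_optical_constants", class(out))
  out
}

#' Absorption coefficient at a target frequency
#'
#' Linear interpolation of `alpha(nu)` between the two grid frequencies
#' bracketing the target. Conventionally the target is 1 THz: high
#' signal-to-noise, above the low-frequency loss minimum, and dominated by
#' the vibrational density of states for amorphous solids.
#'
#' @param optics A `thz_optical_constants` tibble.
#' @param target_frequency Frequency, THz; must lie in the usable band.
#' @return The interpolated absorption coefficient, cm^-1.
#' @export
alpha_at <- function(optics, target_frequency = 1) {
  usable <- attr(optics, "usable_band") %||% range(optics$frequency)
  if (target_frequency < usable[1] || target_frequency > usable[2])
    abort_class(sprintf(
      "target frequency %.3g THz is outside the usable band [%.3g, %.3g] THz",
      target_frequency, usable[1], usable[2]), "thztds_band_error")
  approx(optics$frequency, optics$alpha, xout = target_frequency)$y
}
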