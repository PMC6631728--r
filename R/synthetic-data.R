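#' Configure the synthetic reference pulse
#'
#' The synthetic instrument emits a single-cycle wavelet (first derivative of
#' a Gaussian). With the default width of 0.25 ps its spectral magnitude
#' peaks near 0.64 THz and stays above 1% of that peak out to beyond
#' 2.2 THz, matching the usable band of a broadband time-domain
#' spectrometer (0.2--2.2 THz). The real instrument's pulse shape and
#' signal-to-noise ratio are not public; these defaults are explicit
#' stand-ins, chosen only to reproduce the usable band.
#'
#' @param time_span Total length of the sampled trace, ps.
#' @param sample_interval Sampling interval, ps.
#' @param center_delay Arrival time of the pulse centre, ps.
#' @param pulse_width Gaussian width parameter (sigma) of the wavelet, ps.
#' @param amplitude Peak field amplitude, arbitrary units.
#' @param seed Integer seed carried in the config for reproducibility of any
#'   stochastic additions; the clean pulse itself is deterministic.
#' @return A validated list of class `pulse_config`.
#' @export
#' @examples
#' cfg <- pulse_config()
#' pulse <- make_reference_pulse(cfg)
pulse_config <- function(time_span = 40, sample_interval = 0.02,
                         center_delay = 10, pulse_width = 0.25,
                         amplitude = 1, seed = 1L) {
  cfg <- list(time_span = time_span, sample_interval = sample_interval,
              center_delay = center_delay, pulse_width = pulse_width,
              amplitude = amplitude, seed = as.integer(seed))
  for (f in c("time_span", "sample_interval", "center_delay", "pulse_width",
              "amplitude")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      abort_config(f, "must be a single finite number")
  }
  if (cfg$time_span <= 0) abort_config("time_span", "must be > 0")
  if (cfg$sample_interval <= 0) abort_config("sample_interval", "must be > 0")
  if (cfg$pulse_width <= 0) abort_config("pulse_width", "must be > 0")
  n <- floor(cfg$time_span / cfg$sample_interval)
  if (n < 64)
    abort_config("time_span",
                 "together with sample_interval must give at least 64 samples")
  structure(cfg, class = "pulse_config")
}

new_waveform <- function(time, amplitude, label = NULL, metadata = list()) {
  out <- tibble(time = time, amplitude = amplitude)
  attr(out, "label") <- label
  attr(out, "metadata") <- metadata
  class(out) <- c("thz_waveform", class(out))
  out
}

validate_waveform <- function(wave, arg = "wave") {
  if (!is.data.frame(wave) || !all(c("time", "amplitude") %in% names(wave)))
    abort_class(sprintf("`%s` must have columns `time` and `amplitude`", arg),
                "thztds_input_error")
  if (nrow(wave) < 64)
    abort_class(sprintf("`%s` must have at least 64 samples", arg),
                "thztds_input_error")
  dt <- diff(wave$time)
  if (max(abs(dt - dt[1])) > 1e-9)
    abort_class(sprintf("`%s` is not uniformly sampled (grid deviation > 1e-9 ps)", arg),
                "thztds_sampling_error")
  invisible(wave)
}

#' Generate the clean reference pulse
#'
#' Returns the single-cycle reference waveform defined by a [pulse_config()]:
#' a first-derivative-of-Gaussian wavelet centred at `center_delay`, scaled
#' so its extreme value equals `amplitude`. Its time integral is zero (the
#' wavelet is antisymmetric) and the result is bit-for-bit deterministic for
#' a given config.
#'
#' @param config A [pulse_config()].
#' @return A `thz_waveform` tibble with columns `time` (ps) and `amplitude`.
#' @export
make_reference_pulse <- function(config = pulse_config()) {
  if (!inherits(config, "pulse_config")) config <- do.call(pulse_config, config)
  n <- floor(config$time_span / config$sample_interval)
  t <- (seq_len(n) - 1) * config$sample_interval
  u <- (t - config$center_delay) / config$pulse_width
  # peak of |u exp(-u^2/2)| is exp(-1/2) at u = 1; rescale so peak = amplitude
  amp <- -config$amplitude * u * exp(0.5 - u^2 / 2)
  new_waveform(t, amp, label = "reference",
               metadata = list(pulse = unclass(config)))
}

#' Describe a material's terahertz optical constants
#'
#' A tibble of refractive index and absorption coefficient on a frequency
#' grid, used as ground truth by the forward model. Scalars are recycled
#' over the grid, which is convenient for dispersionless test materials.
#'
#' @param n Refractive index, `>= 1`, scalar or one value per frequency.
#' @param alpha Absorption coefficient, cm^-1, `>= 0`.
#' @param frequency Strictly increasing positive frequency grid, THz. The
#'   default covers the instrument band 0.2--2.2 THz with margin.
#' @return A tibble with columns `frequency`, `n`, `alpha`.
#' @export
material_optics <- function(n, alpha, frequency = seq(0.05, 2.6, by = 0.05)) {
  if (any(!is.finite(frequency)) || any(frequency <= 0) ||
      any(diff(frequency) <= 0))
    abort_config("frequency", "must be strictly increasing and positive")
  n <- rep_len(n, length(frequency))
  alpha <- rep_len(alpha, length(frequency))
  if (any(!is.finite(n)) || any(n < 1))
    abort_config("n", "must be finite and >= 1 everywhere")
  if (any(!is.finite(alpha)) || any(alpha < 0))
    abort_config("alpha", "must be finite and >= 0 everywhere")
  tibble(frequency = frequency, n = n, alpha = alpha)
}

#' Describe the sample slab geometry
#'
#' @param thickness_um Sample (tablet) thickness, micrometres; the
#'   experiment this emulates used compacts of 300--650 um.
#' @param mode `"free_standing"` for a slab in vacuum/nitrogen, or
#'   `"quartz_windowed"` for a tablet sandwiched between z-cut quartz
#'   windows, with the reference beam passing an equal-length quartz path.
#' @param window_index_nq Refractive index of the quartz windows (default
#'   2.11, the THz value for z-cut crystalline quartz).
#' @param window_thickness_mm Window thickness, mm (default 2.05). Only used
#'   for metadata/echo bookkeeping; window absorption cancels in the ratio.
#' @return A list of class `slab_geometry`.
#' @export
slab_geometry <- function(thickness_um, mode = c("free_standing", "quartz_windowed"),
                          window_index_nq = 2.11, window_thickness_mm = 2.05) {
  mode <- arg_match(mode)
  if (!is.numeric(thickness_um) || length(thickness_um) != 1 ||
      !is.finite(thickness_um) || thickness_um <= 0)
    abort_config("thickness_um", "must be a single positive number")
  if (mode == "quartz_windowed" &&
      (!is.finite(window_index_nq) || window_index_nq <= 1))
    abort_config("window_index_nq", "must be > 1 in quartz_windowed mode")
  structure(list(thickness_um = thickness_um, mode = mode,
                 window_index_nq = window_index_nq,
                 window_thickness_mm = window_thickness_mm),
            class = "slab_geometry")
}

validate_geometry <- function(geometry) {
  if (!inherits(geometry, "slab_geometry"))
    abort_class("`geometry` must be created by slab_geometry()",
                "thztds_input_error")
  invisible(geometry)
}

# reference index seen by the sample beam: vacuum for a free-standing slab,
# quartz for the windowed sandwich (phase referenced to an equal quartz path)
ref_index <- function(geometry) {
  if (geometry$mode == "free_standing") 1 else geometry$window_index_nq
}

# complex amplitude transfer function of the slab at frequencies nu (THz),
# optics (n, alpha in cm^-1) already interpolated onto nu
slab_transfer_fn <- function(nu, n, alpha_cm, geometry, include_echo = FALSE) {
  nref <- ref_index(geometry)
  d_um <- geometry$thickness_um
  d_cm <- d_um * 1e-4
  fresnel <- 4 * n * nref / (n + nref)^2
  H <- fresnel * exp(-alpha_cm * d_cm / 2) *
    exp(-1i * 2 * pi * nu * (n - nref) * d_um / C_UM_PS)
  if (include_echo) {
    r <- (n - nref) / (n + nref)
    H <- H * (1 + r^2 * exp(-alpha_cm * d_cm) *
                exp(-1i * 2 * pi * nu * 2 * n * d_um / C_UM_PS))
  }
  H
}

# contiguous band (THz) around the spectral peak where magnitude >= frac*peak
magnitude_band <- function(frequency, magnitude, frac = 0.01) {
  pk <- which.max(magnitude)
  ok <- magnitude >= frac * magnitude[pk]
  lo <- pk
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- pk
  while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
  c(frequency[lo], frequency[hi])
}

#' Forward-model transmission through a slab
#'
#' Multiplies the reference spectrum by the analytic slab transfer function
#' and inverse-transforms, giving the waveform that would be measured after
#' the sample. For a free-standing slab
#' \deqn{H(\nu) = \frac{4n}{(n+1)^2} e^{-\alpha d/2} e^{-i 2\pi\nu (n-1) d / c},}
#' i.e. a Fresnel interface loss, bulk absorption of the field, and the
#' excess phase delay of the slab. In quartz-windowed mode the interface
#' factor becomes \eqn{4 n n_q/(n+n_q)^2} and the phase is referenced to an
#' equal-length quartz path. With `include_echo = TRUE` one Fabry-Perot
#' round trip (internal reflection off both faces, delayed by `2nd/c`) is
#' added; higher-order echoes are negligible at these thicknesses.
#'
#' The model is linear in the input field and deterministic.
#'
#' @param reference A `thz_waveform` (e.g. from [make_reference_pulse()]).
#' @param optics A [material_optics()] tibble; its grid must cover the part
#'   of the pulse's usable band inside the instrument band, otherwise a
#'   band-coverage error is raised. Outside its grid the optics are
#'   extended as constants.
#' @param geometry A [slab_geometry()].
#' @param include_echo Add the first Fabry-Perot echo?
#' @return A `thz_waveform` on the same time grid.
#' @export
propagate_slab <- function(reference, optics, geometry, include_echo = FALSE) {
  validate_waveform(reference, "reference")
  validate_geometry(geometry)
  if (!is.data.frame(optics) || !all(c("frequency", "n", "alpha") %in% names(optics)))
    abort_class("`optics` must have columns frequency, n, alpha",
                "thztds_input_error")

  x <- reference$amplitude
  n_samp <- length(x)
  dt <- reference$time[2] - reference$time[1]
  X <- fft(x)
  k <- seq_len(n_samp) - 1
  ks <- ifelse(k <= n_samp %/% 2, k, k - n_samp)
  f_signed <- ks / (n_samp * dt)   # THz
  fa <- abs(f_signed)

  # band coverage: the pulse's >=1% band clipped to the instrument band must
  # lie inside the optics grid
  pos <- f_signed > 0
  pband <- magnitude_band(f_signed[pos], Mod(X[pos]))
  need <- c(max(pband[1], INSTRUMENT_BAND[1]), min(pband[2], INSTRUMENT_BAND[2]))
  if (need[1] < min(optics$frequency) || need[2] > max(optics$frequency))
    abort_class(sprintf(
      "optics grid [%.3g, %.3g] THz does not cover the pulse band [%.3g, %.3g] THz",
      min(optics$frequency), max(optics$frequency), need[1], need[2]),
      "thztds_band_error")

  ni <- approx(optics$frequency, optics$n, xout = fa, rule = 2)$y
  ai <- approx(optics$frequency, optics$alpha, xout = fa, rule = 2)$y
  H <- slab_transfer_fn(fa, ni, ai, geometry, include_echo)
  H[f_signed < 0] <- Conj(H[f_signed < 0])
  y <- Re(fft(X * H, inverse = TRUE)) / n_samp
  new_waveform(reference$time, y, label = "sample",
               metadata = c(attr(reference, "metadata"),
                            list(geometry = unclass(geometry),
                                 include_echo = include_echo)))
}

#' Define the ground-truth temperature dependence of absorption
#'
#' The temperature dependence of the absorption coefficient at 1 THz of an
#' amorphous solid is modelled as a continuous three-region piecewise linear
#' ("hinge") curve: slope `m1` below the beta-relaxation onset `t_beta`,
#' `m2` between `t_beta` and the alpha-relaxation onset `t_alpha`, and `m3`
#' above. Replicate measurements add independent Gaussian noise.
#'
#' @param m1,m2,m3 Region slopes, cm^-1 K^-1.
#' @param t_beta,t_alpha Breakpoint temperatures, K, with `t_beta < t_alpha`.
#' @param alpha_at_tmin Absorption coefficient at the lowest grid
#'   temperature, cm^-1. Default 10 cm^-1, a typical low-temperature value
#'   for an amorphous polymer compact at 1 THz.
#' @param noise_sigma Replicate noise standard deviation, cm^-1.
#' @param seed Integer; replicate `r` draws its noise from seed `seed + r`.
#' @return A list of class `transition_model`.
#' @export
transition_model <- function(m1, m2, m3, t_beta, t_alpha,
                             alpha_at_tmin = 10, noise_sigma = 0.3,
                             seed = 1L) {
  for (f in c("m1", "m2", "m3", "t_beta", "t_alpha", "alpha_at_tmin",
              "noise_sigma")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      abort_config(f, "must be a single finite number")
  }
  if (t_beta >= t_alpha) abort_config("t_beta", "must be < t_alpha")
  if (noise_sigma < 0) abort_config("noise_sigma", "must be >= 0")
  structure(list(m1 = m1, m2 = m2, m3 = m3, t_beta = t_beta,
                 t_alpha = t_alpha, alpha_at_tmin = alpha_at_tmin,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "transition_model")
}

# continuous hinge evaluation of a transition model
hinge_alpha <- function(model, temperature, t_min) {
  model$alpha_at_tmin +
    model$m1 * (temperature - t_min) +
    (model$m2 - model$m1) * pmax(0, temperature - model$t_beta) +
    (model$m3 - model$m2) * pmax(0, temperature - model$t_alpha)
}

#' Generate replicate temperature series of absorption at 1 THz
#'
#' Evaluates the hinge model of a [transition_model()] on a regular
#' temperature grid and adds independent Gaussian replicate noise. The
#' default grid (90--360 K in 10 K steps) follows the cryostat protocol of
#' the experiment this emulates. Replicates are seeded deterministically
#' (`model$seed + replicate`), so regeneration reproduces every replicate
#' exactly while replicates differ from one another.
#'
#' @param model A [transition_model()].
#' @param t_min,t_max,step Temperature grid, K.
#' @param n_replicates Number of replicate series (default 3, matching the
#'   `n = 3` replicate tablets of the emulated study).
#' @return A tibble with columns `temperature` (K), `alpha` (cm^-1) and
#'   `replicate` (integer), in long format.
#' @export
#' @examples
#' make_temperature_series(
#'   transition_model(0.0026, 0.0237, 0.070, 167, 318, noise_sigma = 0))
make_temperature_series <- function(model, t_min = 90, t_max = 360,
                                    step = 10, n_replicates = 3) {
  if (!inherits(model, "transition_model"))
    abort_class("`model` must be created by transition_model()",
                "thztds_input_error")
  if (step <= 0) abort_config("step", "must be > 0")
  if (!(t_min < model$t_beta && model$t_alpha < t_max))
    abort_config("t_beta",
                 "and t_alpha must lie strictly inside (t_min, t_max)")
  temperature <- seq(t_min, t_max, by = step)
  clean <- hinge_alpha(model, temperature, t_min)
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    noise <- if (model$noise_sigma > 0) {
      withr::with_seed(model$seed + r,
                       rnorm(length(temperature), 0, model$noise_sigma))
    } else rep(0, length(temperature))
    tibble(temperature = temperature, alpha = clean + noise,
           replicate = as.integer(r))
  })
}
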