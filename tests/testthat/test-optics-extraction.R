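test_that("frequency transform behaves as a Fourier pair", {
  dt <- 0.02
  t <- seq(0, 40 - dt, by = dt)
  cosine <- tibble::tibble(time = t, amplitude = cos(2 * pi * 1.0 * t))
  spec <- to_frequency_domain(cosine, taper_fraction = 0, pad_factor = 1)
  expect_equal(spec$frequency[which.max(Mod(spec$value))], 1.0,
               tolerance = 1e-9)

  # Parseval under the unnormalised DFT: sum x^2 = sum |X|^2 / N over the
  # full transform (positive half doubled, DC and Nyquist counted once)
  x <- withr::with_seed(11, rnorm(256))
  x <- x - mean(x)
  wav <- tibble::tibble(time = seq(0, by = 0.05, length.out = 256),
                        amplitude = x)
  spec <- to_frequency_domain(wav, taper_fraction = 0, pad_factor = 1)
  m2 <- Mod(spec$value)^2
  k <- length(m2)
  spec_energy <- (m2[1] + 2 * sum(m2[2:(k - 1)]) + m2[k]) / 256
  expect_equal(spec_energy, sum(x^2), tolerance = 1e-9)

  # discrete impulse: flat magnitude
  imp <- tibble::tibble(time = seq(0, by = 0.05, length.out = 128),
                        amplitude = c(rep(0, 64), 1, rep(0, 63)))
  ispec <- to_frequency_domain(imp, taper_fraction = 0, pad_factor = 1)
  mag <- Mod(ispec$value[ispec$frequency > 0])
  expect_lt(diff(range(mag)) / mean(mag), 1e-9)
})

test_that("non-uniform sampling is rejected", {
  t <- seq(0, 10, length.out = 100)
  t[50] <- t[50] + 0.01
  expect_error(
    to_frequency_domain(tibble::tibble(time = t, amplitude = sin(t))),
    class = "thztds_sampling_error")
})

test_that("transfer function handles identity, delay and scaling", {
  ref <- make_reference_pulse()
  rs <- to_frequency_domain(ref)

  H <- transfer_function(rs, rs)
  sel <- H$frequency >= 0.2 & H$frequency <= 2.2
  expect_equal(Mod(H$value[sel]), rep(1, sum(sel)), tolerance = 1e-12)
  expect_equal(H$phase_unwrapped[sel], rep(0, sum(sel)), tolerance = 1e-9)

  # 1 ps delay: unwrapped anchored phase at 1 THz is -2*pi
  shifted <- ref
  shifted$amplitude <- c(rep(0, 50), ref$amplitude[1:(nrow(ref) - 50)])
  Hd <- transfer_function(to_frequency_domain(shifted), rs)
  i1 <- which.min(abs(Hd$frequency - 1))
  expect_equal(Hd$phase_unwrapped[i1], -2 * pi, tolerance = 1e-6)

  half <- ref
  half$amplitude <- 0.5 * ref$amplitude
  Hs <- transfer_function(to_frequency_domain(half), rs)
  expect_equal(Mod(Hs$value[sel]), rep(0.5, sum(sel)), tolerance = 1e-12)
  expect_equal(Hs$phase_unwrapped[sel], rep(0, sum(sel)), tolerance = 1e-9)

  zero <- ref
  zero$amplitude <- 0 * ref$amplitude
  expect_error(transfer_function(rs, to_frequency_domain(zero)),
               class = "thztds_degenerate_reference_error")
})

test_that("phase anchoring is invariant to whole-curve 2*pi*k offsets", {
  ref <- make_reference_pulse()
  rs <- to_frequency_domain(ref)
  geom <- slab_geometry(500, "free_standing")
  sam <- propagate_slab(ref, material_optics(1.7, 20), geom)
  H <- transfer_function(to_frequency_domain(sam), rs)
  base <- extract_optical_constants(H, geom)
  for (k in c(-3L, 2L, 11L)) {
    Hk <- H
    Hk$phase_unwrapped <- anchor_phase(Hk$frequency,
                                       Hk$phase_unwrapped + 2 * pi * k)
    shifted <- extract_optical_constants(Hk, geom)
    expect_equal(shifted$n, base$n, tolerance = 1e-12)
  }
})

test_that("echo gating opens at main peak + 2nd/c and leaves clean traces alone", {
  ref <- make_reference_pulse()
  geom <- slab_geometry(500, "free_standing")
  gated <- gate_reflections(ref, geom, n_estimate = 1.6)
  gate_ps <- attr(gated, "metadata")$gate_ps
  t_peak <- ref$time[which.max(abs(ref$amplitude))]
  expect_equal(gate_ps - t_peak, 2 * 1.6 * 500 / 299.792458,
               tolerance = 1e-9)  # 5.33 ps
  # echo-free pulse: untouched outside the roll-off region
  before_roll <- ref$time <= gate_ps - attr(gated, "metadata")$gate_rolloff_ps
  expect_identical(gated$amplitude[before_roll], ref$amplitude[before_roll])
  expect_error(gate_reflections(ref, geom, n_estimate = 0.9),
               class = "thztds_config_error")
})

test_that("gating strictly reduces the Fabry-Perot ripple of |H|", {
  ref <- make_reference_pulse()
  rs <- to_frequency_domain(ref, 0.05, 2)
  geom <- slab_geometry(500, "free_standing")
  echoed <- propagate_slab(ref, material_optics(1.6, 10), geom,
                           include_echo = TRUE)
  gated <- gate_reflections(echoed, geom, n_estimate = 1.6)
  expect_lt(transfer_ripple(gated, rs), transfer_ripple(echoed, rs))
})

test_that("the analytic inverse recovers an identity and a closed-form slab", {
  geom <- slab_geometry(500, "free_standing")
  f <- seq(0.0125, 2.5, by = 0.0125)

  H1 <- transfer_from_spectrum(f, complex(real = rep(1, length(f))))
  oc1 <- extract_optical_constants(H1, geom)
  expect_equal(oc1$n, rep(1, nrow(oc1)), tolerance = 1e-12)
  expect_equal(oc1$alpha, rep(0, nrow(oc1)), tolerance = 1e-12)

  delay <- (1.6 - 1) * 500 / 299.792458  # ps
  Hv <- 4 * 1.6 / 2.6^2 * exp(-1i * 2 * pi * f * delay)
  oc <- extract_optical_constants(transfer_from_spectrum(f, Hv), geom)
  i1 <- which.min(abs(oc$frequency - 1))
  expect_equal(oc$n[i1], 1.6, tolerance = 1e-9)
  expect_equal(oc$alpha[i1], 0, tolerance = 1e-9)
})

test_that("forward model then extraction round-trips constant optics", {
  ref <- make_reference_pulse()
  rs <- to_frequency_domain(ref)
  check_roundtrip <- function(n_true, a_true, d_um, mode) {
    geom <- slab_geometry(d_um, mode)
    sam <- propagate_slab(ref, material_optics(n_true, a_true), geom)
    oc <- extract_optical_constants(
      transfer_function(to_frequency_domain(sam), rs), geom)
    sel <- oc$frequency >= 0.4 & oc$frequency <= 1.8
    expect_lt(max(abs(oc$n[sel] - n_true)) / n_true, 0.01)
    expect_lt(max(abs(oc$alpha[sel] - a_true)),
              max(0.01 * a_true, 0.5))
  }
  check_roundtrip(1.6, 10, 500, "free_standing")
  check_roundtrip(1.6, 10, 500, "quartz_windowed")
  # property sweep: random materials in the physical range
  withr::with_seed(5, {
    for (i in 1:6) {
      check_roundtrip(runif(1, 1.05, 3), runif(1, 0, 100),
                      runif(1, 300, 650),
                      sample(c("free_standing", "quartz_windowed"), 1))
    }
  })
})

test_that("round trip is consistent when the slab is halved", {
  ref <- make_reference_pulse()
  rs <- to_frequency_domain(ref)
  for (d in c(600, 300)) {
    geom <- slab_geometry(d, "free_standing")
    sam <- propagate_slab(ref, material_optics(2.0, 30), geom)
    oc <- extract_optical_constants(
      transfer_function(to_frequency_domain(sam), rs), geom)
    sel <- oc$frequency >= 0.4 & oc$frequency <= 1.8
    expect_lt(max(abs(oc$n[sel] - 2.0)) / 2.0, 0.01)
    expect_lt(max(abs(oc$alpha[sel] - 30)), max(0.3, 0.5))
  }
})

test_that("a rising absorption spectrum is reproduced as rising", {
  ref <- make_reference_pulse()
  rs <- to_frequency_domain(ref)
  geom <- slab_geometry(500, "free_standing")
  fgrid <- seq(0.05, 2.6, by = 0.05)
  optics <- material_optics(1.6, 20 * fgrid / max(fgrid), fgrid)
  sam <- propagate_slab(ref, optics, geom)
  oc <- extract_optical_constants(
    transfer_function(to_frequency_domain(sam), rs), geom)
  sel <- oc$frequency >= 0.4 & oc$frequency <= 1.8
  expect_true(all(diff(oc$alpha[sel]) > -1e-6))
})

test_that("alpha_at interpolates linearly and respects the usable band", {
  oc <- tibble::tibble(frequency = c(0.98, 1.0, 1.02), n = 1.5,
                       alpha = c(10, 12.5, 14))
  attr(oc, "usable_band") <- c(0.2, 2.2)
  expect_identical(alpha_at(oc, 1.0), 12.5)

  oc2 <- tibble::tibble(frequency = c(0.98, 1.02), n = 1.5, alpha = c(10, 14))
  attr(oc2, "usable_band") <- c(0.2, 2.2)
  expect_equal(alpha_at(oc2, 1.0), 12.0, tolerance = 1e-12)

  expect_error(alpha_at(oc, 2.5), class = "thztds_band_error")
})
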