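# Published per-region slope triples (cm^-1 K^-1) and transition
# temperatures (K) for the six PLGA microsphere formulations; used as
# ground truth throughout the suite.
table1_models <- list(
  plga5050_blank = list(m = c(0.0026, 0.0237, 0.070), tg = c(167, 318)),
  plga5050_low   = list(m = c(0.0010, 0.021, 0.074),  tg = c(168, 320)),
  plga5050_high  = list(m = c(0.014, 0.023, 0.095),   tg = c(219, 330)),
  plga7525_blank = list(m = c(0.0087, 0.026, 0.043),  tg = c(179, 313)),
  plga7525_low   = list(m = c(0.0060, 0.022, 0.057),  tg = c(192, 320)),
  plga7525_high  = list(m = c(0.0078, 0.022, 0.067),  tg = c(215, 327))
)

as_model <- function(entry, noise_sigma = 0, seed = 1L) {
  transition_model(entry$m[1], entry$m[2], entry$m[3],
                   entry$tg[1], entry$tg[2],
                   noise_sigma = noise_sigma, seed = seed)
}

# independent brute-force three-segment fitter: enumerates every valid
# partition with lm() and applies the same admissibility rule, entirely
# separate numerics from the package's cumulative-sum search
brute_force_fit3 <- function(x, y, minp = 4, parallel_tol = 1e-12) {
  n <- length(x)
  best <- NULL
  for (i in minp:(n - 2 * minp)) {
    for (j in (i + minp):(n - minp)) {
      idx <- list(1:i, (i + 1):j, (j + 1):n)
      fits <- lapply(idx, function(k) lm(y[k] ~ x[k]))
      ms <- vapply(fits, function(f) unname(coef(f)[2]), 0)
      bs <- vapply(fits, function(f) unname(coef(f)[1]), 0)
      if (abs(ms[1] - ms[2]) < parallel_tol ||
          abs(ms[2] - ms[3]) < parallel_tol) next
      tb <- (bs[2] - bs[1]) / (ms[1] - ms[2])
      ta <- (bs[3] - bs[2]) / (ms[2] - ms[3])
      if (!is.finite(tb) || !is.finite(ta)) next
      if (tb >= ta || tb < x[1] || tb > x[j] || ta < x[i + 1] || ta > x[n]) next
      sse <- sum(vapply(fits, function(f) sum(residuals(f)^2), 0))
      if (is.null(best) || sse < best$sse - 1e-15) {
        best <- list(i = i, j = j, sse = sse, tb = tb, ta = ta)
      }
    }
  }
  best
}

# detrended ripple of |H| over a band: sd of residuals of a cubic trend
transfer_ripple <- function(wave, ref_spec, band = c(0.5, 1.5)) {
  H <- transfer_function(to_frequency_domain(wave, 0.05, 2), ref_spec)
  sel <- H$frequency >= band[1] & H$frequency <= band[2]
  m <- Mod(H$value[sel])
  f <- H$frequency[sel]
  sd(residuals(lm(m ~ poly(f, 3))))
}
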