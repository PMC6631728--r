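# thztds

Variable-temperature terahertz time-domain spectroscopy (THz-TDS) of
amorphous solids, end to end in R: from time-domain electric-field
waveforms to frequency-dependent optical constants, to the temperature
dependence of the absorption coefficient at 1 THz, to the two glass
transitions of a glassy polymer.

**Who it is for.** Anyone analysing cryostat THz-TDS transmission sweeps
of amorphous materials — e.g. pharmaceutical polymer matrices such as
PLGA microsphere compacts — where the onsets of local ($\beta$) and
large-scale ($\alpha$) molecular mobility show up as slope changes in
$\alpha(1\,\mathrm{THz})$ versus temperature.

## The method

1. **Transfer-function extraction.** The complex ratio of sample to
   reference spectra of a slab of thickness $d$ is
   $H(\nu) = \frac{4n}{(n+1)^2} e^{-\alpha d/2} e^{-i 2\pi\nu (n-1) d/c}$,
   inverted analytically bin by bin:
   $n(\nu) = 1 + c\,(-\varphi)/(2\pi\nu d)$ and
   $\alpha(\nu) = -(2/d)\ln[|H|(n+1)^2/(4n)]$, with the unwrapped phase
   anchored to zero at zero frequency and Fabry–Pérot echoes removed by
   time-domain gating. A quartz-windowed sample-holder mode
   ($4nn_q/(n+n_q)^2$, quartz-referenced phase) is included.
2. **Three-segment fitting.** $\alpha(1\,\mathrm{THz};T)$ is fitted by
   three independent least-squares lines over an exhaustively searched
   partition of the temperature points; the glass transitions are the
   intersections of adjacent lines, $T = (b_2-b_1)/(m_1-m_2)$:
   $T_{g,\beta}$ from regions 1–2, $T_{g,\alpha}$ from regions 2–3, with
   standard errors by first-order covariance propagation.
3. **Synthetic instrument.** A physics-based generator (single-cycle
   pulses, slab transmission with Fresnel losses, absorption, delay and
   one echo; hinge-model temperature series with seeded replicate noise)
   makes the whole chain testable against known ground truth.

Everything is a tibble in, tibble out; fitted objects support `tidy()`,
`glance()` and `autoplot()`. See the vignette
(`vignettes/thz-glass-transitions.Rmd`) for the full methods account.

## Worked example

```r
library(thztds)

model  <- transition_model(0.0026, 0.0237, 0.070,
                           t_beta = 167, t_alpha = 318,
                           noise_sigma = 0.1, seed = 2)
series <- make_temperature_series(model)   # 90-360 K, 10 K, 3 replicates
fit    <- fit_three_segments(series)
fit
#> Three-segment linear fit of alpha(1 THz) vs temperature
#>   28 points, boundaries after points 8 and 23, total SSE 0.07365
#>   region 1: m = 0.002861 +/- 0.0009 cm^-1 K^-1 (n = 8)
#>   region 2: m = 0.02383 +/- 0.00034 cm^-1 K^-1 (n = 15)
#>   region 3: m = 0.07303 +/- 0.002 cm^-1 K^-1 (n = 5)
#>   Tg_beta  = 167.8 +/- 2.5 K
#>   Tg_alpha = 318.7 +/- 1.2 K
```

The generator's true slopes (0.0026, 0.0237, 0.070 cm⁻¹K⁻¹) and
breakpoints (167 K, 318 K) are recovered to within the reported
uncertainties from replicate-noisy data.

The same applies through the full waveform chain — simulate the slab
transmission at every temperature, extract the optical constants, read
off 1 THz, fit:

```r
cfg <- run_config(
  samples = list(list(label = "PLGA 75:25 blank",
                      model = transition_model(0.0087, 0.026, 0.043,
                                               179, 313, noise_sigma = 0),
                      dsc_K = 317)),
  seed = 1)
run_pipeline(cfg)$report
#> # A tibble: 1 x 12
#>   sample                m1    m1_se     m2  m2_se     m3 m3_se tg_beta_K ...
#> 1 PLGA 75:25 blank 0.00870  3.63e-9 0.0260 3.4e-8 0.0430 3.9e-8      179.
```

with `tg_beta_K = 179.0005` and `tg_alpha_K = 312.9996` against generator
truth 179 / 313 — the extraction stage adds less than a millikelvin of
bias on noiseless waveforms.

A thin command-line front end over the same functions is installed at
`system.file("cli", "thztds.R", package = "thztds")` with subcommands
`simulate`, `extract`, `fit-transitions`, `normalize` and `run-all`.

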