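# sousawave

Passive acoustic monitoring tools for whistling dolphins, built around
the two signal families of the Indo-Pacific humpback dolphin
(*Sousa chinensis*): broadband **echolocation clicks** (tens of
microseconds, peak frequencies near 86 kHz) and tonal **whistles**
(2–16 kHz fundamentals, tens of milliseconds to a second). The package is
aimed at bioacousticians who need a reproducible, testable desk pipeline
from calibrated WAV recordings to population-level acoustic statistics
and a two-group (West/East sub-region) comparison.

## What it implements

* **Click detection** — Teager–Kaiser energy operator
  `Ψ[xₙ] = xₙ² − xₙ₋₁xₙ₊₁`, smoothed by matched-gain Gaussian
  (FWHM 0.10 ms, `σ_G = FWHM/(2√(2 ln 2))`) and rectangular kernels; the
  filter difference ratio `FDR = (h₁ − h₂)/h₁` is ≈0 on stationary noise
  and ≈0.73 at an impulse, thresholded at 0.7. Peak-referenced window
  extraction and a pluggable click/non-click classifier (default: a
  single-hidden-layer `nnet` trained on synthetic scenes).
* **Click measurement** — peak frequency, −3/−6/−10 dB bandwidths
  (contiguous interval around the peak, interpolated crossings),
  95%-energy duration (envelope-energy quantiles), and peak-to-peak SPL
  `20·log₁₀(p_max − p_min)` re 1 µPa.
* **Whistle extraction** — 1024-sample Hanning STFT (hop 512),
  `P = 20·log₁₀|STFT|`; 3×3 median enhancement plus the global offset
  `3·sd(P) − mean(P)`; adaptive thresholding against the mean intensity
  in a radius-15 disk; 8-connected components filtered by width ≥ 11
  columns and max enhanced value ≥ 10; intensity-weighted ridge
  contours; duration/BF/EF/MinF/MaxF/range; six-way shape typing
  (constant, upsweep, downsweep, concave, convex, sinusoidal).
* **Statistics** — Shapiro–Wilk (n ≤ 50) / Kolmogorov–Smirnov (n > 50)
  normality gating, two-tailed Mann–Whitney U (exact enumeration for
  min(n) ≤ 8, tie-corrected normal approximation otherwise), descriptive
  tables, type proportions, and a West/East comparison report (JSON +
  Markdown). Recording sites are assigned to sub-regions by inclusive
  bounding boxes (West 24.30–24.57° N / 117.94–118.16° E, East
  24.45–24.63° N / 118.22–118.50° E).
* **Synthetic scenes** — seeded, byte-reproducible 576 kHz scenes of
  chirped Gaussian-envelope click trains, FM whistles of the six contour
  archetypes, snapping-shrimp-like impulses, vessel and ambient noise,
  with exact ground-truth annotations; population parameters default to
  published field statistics for this population.

See `vignettes/pam-methods.Rmd` for the model details, parameter
defaults, and the design decisions behind them.

## Worked example

Render a synthetic scene with ten 160 dB clicks in 95 dB ambient noise,
detect and measure them:

```r
library(sousawave)

specs <- lapply(seq(0.1, 1.9, by = 0.2), function(t)
  click_synth_spec(carrier_khz = 86, sigma_us = 8, splpp_db = 160,
                   onset_s = t))
scene <- render_scene(scene_config(duration_s = 2, click_specs = specs,
                                   ambient_spl_db = 95, seed = 13))
cands <- detect_candidates(highpass(scene$segment))
length(cands)
#> [1] 10

metrics <- lapply(cands, function(cd)
  measure_click(cd$window, scene$segment$sample_rate))
summarize_metrics(metrics)[c(1, 2, 5, 6), c("parameter", "mean", "sd")]
#>     parameter      mean          sd
#> 1      fp_khz  86.02031 0.067928328
#> 2     bw3_khz  33.09265 0.050925943
#> 5 duration_us  22.17171 0.009644393
#> 6    splpp_db 159.99984 0.007332332
```

(An 8 µs Gaussian envelope gives a ≈22 µs click of ≈33 kHz −3 dB
bandwidth; the detector recovers all ten at their annotated times and
the measured levels sit on the generated 160 dB.)

A whistle and the group comparison:

```r
tone <- whistle_synth_spec("upsweep", duration_ms = 350,
                           freq_anchors_khz = c(5, 9), snr_db = 20,
                           onset_s = 0.8)
scene2 <- render_scene(scene_config(2, whistle_specs = list(tone), seed = 3))
dw <- detect_whistles(scene2$segment)
subset(dw$summary, shape == "upsweep" & duration_ms > 300)
#>  onset_s duration_ms   bf_khz   ef_khz minf_khz maxf_khz range_khz   shape
#>      0.8    350.2222 5.032169 8.979615 5.032169 8.979615  3.947446 upsweep

set.seed(1)
report <- compare_report(list(grouped_samples(
  "fp_khz", west = rnorm(100, 87, 5), east = rnorm(80, 80, 5), "kHz")))
print(report)
#> Two-group comparison (two-tailed Mann-Whitney U, alpha = 0.05 )
#>   fp_khz kHz: West 87.5 ± 4.5 vs East 80.0 ± 4.9, U = 6947, p = 2.18e-17 *
```

A thin command-line wrapper over the same functions ships at
`inst/cli/pam` (subcommands `synth`, `prep`, `detect-clicks`,
`detect-whistles`, `compare`); an example scene configuration is in
`inst/extdata/example_scene.yaml`.

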