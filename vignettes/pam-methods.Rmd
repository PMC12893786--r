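---
title: "Detecting and measuring dolphin clicks and whistles: methods"
author: "sousawave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and measuring dolphin clicks and whistles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sousawave)
```

## The problem

Indo-Pacific humpback dolphins (*Sousa chinensis*) produce two signal
families that passive acoustic monitoring must handle very differently:
**echolocation clicks** — broadband transients tens of microseconds long
with peak frequencies near 80–90 kHz — and **whistles** — tonal,
frequency-modulated calls with fundamentals around 2–16 kHz lasting tens
of milliseconds to a second. `sousawave` implements a complete desk-scale
pipeline for both: a click detector built on the Teager–Kaiser energy
operator, a spectrogram-morphology whistle extractor, the standard
acoustic measurements for each, and the nonparametric two-group protocol
used to compare recordings between sub-regions of a study area (here, the
West/East sub-regions of Xiamen Bay). Because field recordings are bulky
and ground truth for them is scarce, the package also contains a
first-class synthetic-scene generator whose events carry exact
annotations; every detector and measurement stage is validated against
it.

## Click detection

Audio is first high-passed at 5 kHz (4th-order Butterworth, applied
forward–backward so click peaks are not shifted in time; the filter
family and order are this package's choice — only the cutoff is inherited
from standard practice for this recorder band).

The Teager–Kaiser energy operator
\[
\Psi[x_n] = x_n^2 - x_{n-1}x_{n+1}
\]
tracks instantaneous signal energy and responds sharply to transients.
The TKEO series is smoothed by two matched-gain kernels: a Gaussian with
standard deviation $\sigma_G = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ (FWHM
0.10 ms) and a rectangular kernel of identical length whose taps all
equal the mean Gaussian tap, so both kernels have exactly the same total
gain. The *filter difference ratio*
\[
\mathrm{FDR}[n] = \frac{h_1[n]-h_2[n]}{h_1[n]}
\]
(h1 Gaussian-smoothed, h2 rectangular-smoothed) is near zero on
stationary noise — the equal gains cancel — and rises toward
$1-\bar g/g_{\max} \approx 0.73$ at an isolated impulse, which is why the
0.7 threshold separates click-like transients from the stationary
background. Contiguous above-threshold runs are merged (1.0 ms
refractory, our choice), and each run yields one candidate at its TKEO
maximum.

A window is then grown symmetrically from the envelope peak until the
Hilbert envelope stays 20 dB below the peak for 10 consecutive samples on
each side, capped at ±150 µs. The merge interval, the window-growth rule
and the kernel length (2N+1 spanning four FWHMs, capturing >99.9% of the
Gaussian mass) are package choices, fixed and configurable, made so event
counts are reproducible.

Candidates still include other broadband transients, most prominently
snapping-shrimp impulses. A pluggable classifier — by default a
single-hidden-layer feed-forward network (32 logistic units, `nnet`)
trained on synthetic scenes with known labels — scores each candidate
from six level-independent features (95%-energy duration, peak frequency,
−3 dB bandwidth, spectral centroid, crest factor, fraction of energy
above 100 kHz). Any function mapping the feature vector to a score in
[0, 1] can replace it. The default classifier is trained on synthetic
contrasts only; its measured accuracy on synthetic held-out data says
nothing about accuracy on real recordings, and no published-network
performance is claimed or reproduced.

## Click measurements

From each window the package reports the conventional parameters: peak
frequency (argmax of the magnitude spectrum of the window zero-padded to
≥4096 points, ≈141 Hz resolution at 576 kHz); −3/−6/−10 dB bandwidths
(width of the contiguous interval around the peak where power stays
within x dB of it, linearly interpolated at the crossings — the
contiguous convention avoids sidelobe inflation); peak-to-peak sound
pressure level $20\log_{10}(p_{\max}-p_{\min})$ re 1 µPa; and duration.

**Duration convention.** Duration is the central 95% interval of
cumulative energy. The package accumulates the *squared Hilbert
envelope* rather than the raw squared pressure: for near-single-cycle
pulses the carrier phase puts a strong ripple in the raw energy cdf, and
the 2.5%/97.5% quantiles of the raw form deviate by up to ~10% from the
envelope value (this is a property of the waveform, not of sampling — it
persists at 5 MHz sampling). The envelope form agrees with the
closed-form Gaussian-envelope result $\tau_{95} = 2.772\,\sigma$ within
2% across the σ range of interest at 576 kHz. The envelope is computed on
a zero-padded, 4× band-limited-interpolated copy of the window: padding
suppresses the circular wrap-around of the analytic transform on short
windows and the oversampling removes quantile discretisation when the
envelope spans only a few samples. The raw-energy variant
(`"energy95_raw"`) and a −10 dB envelope width (`"env10db"`) remain
selectable.

## Whistle extraction

Long recordings are segmented into frames of 65 792 samples overlapping
by 13 824 to bound memory; short segments are processed whole, and
duplicate detections in overlapped regions are removed by onset proximity
(<5 ms, our policy). Each segment is transformed with a 1024-sample
Hanning STFT (hop 512, our choice — 50% of the window; it places the
11-column width rule at ≈9.8 ms, below any plausible whistle) into
$P = 20\log_{10}|STFT|$, floored at −120 dB.

Enhancement applies an exact 3×3 median filter (reflected padding)
followed by the global scalar offset $3\,\mathrm{sd}(P)-\overline P$
computed over the pre-median matrix: $P' = \mathrm{med}(P) + 3\,
\mathrm{sd}(P) - \overline P$. The offset is one number for the whole
matrix, so it preserves pixel ordering; it matters only to the absolute
intensity filter below. (A per-pixel normalization would be an
alternative reading of such an enhancement step; the global form is
implemented as stated, and only interacts with the `min_peak` rule.)

**Adaptive threshold.** Each pixel is compared against the mean intensity
over the discrete Euclidean disk of radius 15 pixels (clipped at the
edges). *Intensity is averaged on the linear power scale.* This choice is
load-bearing: thresholding dB values against a local dB mean retains
about half of any homogeneous noise field — above the 8-connected site
percolation threshold (~0.407) — so noise would form image-spanning
connected components that no width or intensity rule could remove.
Averaging linear power retains $1/e \approx 37\%$ of noise pixels,
keeping noise components small enough for the width filter, which is the
regime the morphological cleanup is designed for. The dB-mean variant is
available via `adaptive_threshold(..., scale = "db")`.

Retained pixels are labeled by 8-connected component analysis (diagonal
contact joins regions). Components narrower than 11 time columns are
discarded as click interference; components whose maximum enhanced value
is below 10 (on the enhanced dB scale — the only matrix in play at that
step) are discarded as noise. For each surviving region the ridge is the
per-column linear-magnitude-weighted centroid of the region's pixels,
single-column gaps are linearly interpolated and flagged, and the contour
is smoothed with a 5-point running median.

By default the whistle stage analyses the 0–32 kHz band only: the
fundamentals of interest lie at 2–16 kHz, bins above carry no tonal
information, and restricting the band makes the stage roughly an order
of magnitude faster. `max_freq_khz = NULL` restores full-band analysis.

**Metrics and shape types.** Duration is `(columns − 1) × hop / fs`;
beginning/ending frequency are the first/last ridge values; minimum and
maximum frequency are the ridge extrema; range is their difference.
Shape classification uses deterministic rules with tolerance
$\delta = \max(0.25\ \mathrm{kHz}, 5\%\ \text{of mean frequency})$:
*constant* if the ridge range is below $2\delta$; otherwise interior
turning points are counted with δ-hysteresis — 0 turns gives
*upsweep*/*downsweep* by the sign of end minus start, 1 turn gives
*convex* (interior maximum) or *concave* (interior minimum), ≥2 turns
gives *sinusoidal*.

## Two-group statistics

Normality is assessed per group with Shapiro–Wilk for n ≤ 50 and a
one-sample Kolmogorov–Smirnov against a normal with the sample's own
mean and SD for n > 50 (the Lilliefors-style estimated-parameter reading;
the package documents this choice in its output). Group differences use
the two-tailed Mann–Whitney U test: U is reported for the first (west)
group from joint midranks; for min(n) ≤ 8 the two-tailed p comes from
exact enumeration of all group labelings (valid under ties), otherwise
from the normal approximation with tie-corrected variance and no
continuity correction. Per-parameter p-values are reported without
multiplicity correction at two-tailed α = 0.05, matching the conventional
reporting of such surveys; Holm and friends are available behind the
`p_adjust` argument. Monthly vessel-density values are treated as the
sampling units for the traffic comparison.

## The synthetic-scene generator

The generator is the package's ground-truth instrument, and its defaults
*are* the study conditions the validation suite runs under: 576 kHz mono
scenes containing

* **clicks** — linearly chirped Gaussian-envelope (Gabor-like) pulses
  $g(t) = A\,e^{-t^2/2\sigma^2}\cos 2\pi(f_c t + ct^2/2)$ sampled over
  ±4σ, scaled so the peak-to-peak pressure matches the requested level.
  No published source-waveform model exists for these clicks; the
  chirped-Gabor form is this package's minimal model, chosen because the
  chirp decouples duration from bandwidth so both population marginals
  can be matched independently (`solve_chirp_rate()` inverts the
  bandwidth measurement numerically);
* **whistles** — phase-continuous FM tones whose frequency track
  interpolates anchor values per archetype (flat; linear sweeps;
  quadratic through an interior extremum; piecewise raised-cosine through
  alternating anchors), harmonics off by default so ridge recovery tests
  are unambiguous;
* **snaps** — instant-attack exponential decays (time constant drawn
  3–6 µs in scenes) on a fast 260→30 kHz downsweep carrier: broadband
  past 150 kHz, 95%-energy duration below 15 µs, spectral centroid ~200
  kHz — deliberately separable from clicks by centroid and duration so
  the classifier has a documented, learnable contrast;
* **noise** — Gaussian ambient noise at a calibrated RMS level, plus
  optional low-passed vessel noise.

Event levels in scenes are specified as RMS SNR: the event's RMS over its
95%-energy support relative to the ambient RMS. Population parameters
are drawn to match published field statistics for this population:
truncated normals (with far physical floors, so recovered means are not
truncation-biased) for click peak frequency (86.4 ± 19.5 kHz, floor 20),
−3 dB bandwidth (53.3 ± 14.6 kHz, floor 15), duration (22.3 ± 6.4 µs,
floor 6) and a plain normal for SPLpp (162.8 ± 9.5 dB); lognormals
parameterised by the printed mean/SD for the strongly right-skewed
whistle duration (247.6 ± 174.2 ms), minimum frequency (5.2 ± 2.2 kHz)
and maximum frequency (7.5 ± 2.7 kHz). A fixed seed renders a
byte-identical scene, and the default hydrophone calibration (−176 dB re
1 V/µPa, 0 dB gain, 1 V full scale) is a typical autonomous-recorder
value — recorders differ, so all SPL outputs carry their calibration.

What the generator does *not* emulate — propagation (absorption,
multipath), source directionality, movement, reverberation, colored or
non-Gaussian ambient statistics — bounds what passing tests show: they
validate the algorithms against their own assumptions, not field
performance. In particular the classifier's synthetic accuracy and the
detector's synthetic precision/recall are properties of this synthetic
contrast only.

## Validation scales and numerical choices

The validation suite (and `scripts/acceptance.R`) uses 2 000-click
recovery runs per click parameter at 25 dB SNR and 1 000-tone runs per
whistle parameter at 20 dB SNR, a 60 s standard detector scene (50 clicks
at 160 dB pp, ambient 95 dB, 1 snap/s, seed 7) and 300 shape-archetype
trials at 15 dB SNR — sizes chosen so the recovered means have standard
errors comfortably inside the tolerances being asserted while the whole
suite stays desk-scale. Known small biases at these conditions, visible
in the recovery tables and deliberately not corrected: the noisy spectral
maximum biases measured −3 dB bandwidth low by ~1 kHz at 25 dB SNR
(threshold referenced to a fluctuating peak), and in-window noise biases
the 95%-energy duration high by well under 1 µs.

Numerical conventions: same-length zero-padded convolution keeps the FDR
aligned with sample indices (long signals via overlap-add FFT blocks);
the disk mean uses FFT convolution with an edge-clipped count, with a
strict-inequality guard of one part in 10⁹ so a constant field yields an
empty mask instead of round-off speckle; the 3×3 median is an exact
19-comparator selection network; zero-magnitude spectrogram bins are
floored at −120 dB; a single-observation SD is reported as 0 and flagged;
and all library randomness flows through caller-supplied seeds with the
caller's RNG state restored.

## Known limitations

* All performance figures are synthetic-scene figures (see above).
* The whistle extractor reports every surviving component; in
  homogeneous noise a sizeable number of small noise components pass the
  width/intensity rules, as they would on real data — downstream review
  (or matching against annotations, as the validation suite does) is
  expected. An optional review export, not an algorithm, stands in for
  manual inspection.
* Overlapping whistles are not separated, and harmonic stacks are not
  fused.
* Click quality screening for reverberation (`screen_reverberant()`) is
  a simple envelope-lobe rule, exposed but off by default, with no claim
  of equivalence to any published selection protocol.
* Source-level back-calculation is out of scope (no ranges available).
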