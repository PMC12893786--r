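fs <- 576000

test_that("click pulses match the Gaussian-envelope closed forms", {
  spec <- click_synth_spec(carrier_khz = 90, sigma_us = 5, splpp_db = 160)
  pulse <- make_click_pulse(spec, fs)
  m <- measure_click(pulse$waveform, fs)
  expect_lt(abs(m$fp_khz - 90), 0.15)
  expect_lt(abs(m$bw3_khz - 53.0), 1.1)
  expect_lt(abs(m$duration_us - 13.9), 0.3)
  # peak-to-peak scaling is exact by construction
  expect_equal(max(pulse$waveform) - min(pulse$waveform), 10^(160 / 20))

  # the closed forms describe the analytic (single-sided) pulse; the
  # carrier is placed high enough that the negative-frequency image of
  # the real waveform stays out of the measured band at every sigma
  for (sig in c(3, 5, 8, 12)) {
    p <- make_click_pulse(click_synth_spec(130, sig, splpp_db = 150), fs)
    m <- measure_click(p$waveform, fs)
    bw_cf <- sqrt(log(2)) / (pi * sig * 1e-6) / 1000
    expect_lt(abs(m$bw3_khz / bw_cf - 1), 0.02)
    expect_lt(abs(m$duration_us / (2.772 * sig) - 1), 0.02)
  }
})

test_that("calibration round-trips across the 120-190 dB range", {
  for (L in seq(120, 190, by = 10)) {
    p <- make_click_pulse(click_synth_spec(86, 5, splpp_db = L), fs)
    expect_lt(abs(measure_click(p$waveform, fs)$splpp_db - L), 0.1)
  }
})

test_that("pulse generation rejects out-of-band instantaneous frequency", {
  expect_error(make_click_pulse(click_synth_spec(300, 5), fs), "Nyquist")
  # strong chirp pushes the band edge over Nyquist within +/-4 sigma
  expect_error(make_click_pulse(click_synth_spec(280, 20,
                                                 chirp_khz_per_us = 5), fs),
               "instantaneous")
})

test_that("solve_chirp_rate inverts the bandwidth measurement", {
  bound <- sqrt(log(2)) / (pi * 5e-6) / 1000
  expect_equal(solve_chirp_rate(bound, 5), 0)
  expect_error(solve_chirp_rate(bound * 0.99, 5), "bound")
  # widening 53 -> 70 kHz sweeps +/-110 kHz across the +/-4 sigma
  # support, so the probe carrier needs that much headroom on each side
  c70 <- solve_chirp_rate(70, 5, carrier_khz = 150)
  p <- make_click_pulse(click_synth_spec(150, 5, chirp_khz_per_us = c70), fs)
  expect_lt(abs(measure_click(p$waveform, fs)$bw3_khz - 70), 0.7)
  # monotone in the target bandwidth
  rates <- vapply(c(55, 60, 65, 70), solve_chirp_rate, 0, sigma_us = 5,
                  carrier_khz = 150)
  expect_true(all(diff(rates) > 0))
})

test_that("whistle waveforms follow their contour archetype", {
  ridge_of <- function(spec) {
    seg <- clean_tone_segment(spec)
    sp <- spectrogram(seg)
    cols <- which(apply(sp$values, 2L, max) > 0)
    apply(sp$values[, cols, drop = FALSE], 2L, which.max)
  }
  r_const <- ridge_of(whistle_synth_spec("constant", 300, 6))
  expect_true(all(abs(r_const - (round(6000 / 562.5) + 1L)) <= 1))

  r_up <- ridge_of(whistle_synth_spec("upsweep", 300, c(5, 9)))
  expect_lt(abs(r_up[1L] * 0.5625 - 5), 0.9)
  expect_lt(abs(r_up[length(r_up)] * 0.5625 - 9), 0.9)

  r_sin <- ridge_of(whistle_synth_spec("sinusoidal", 400, c(6, 8, 6, 8)))
  turns <- sum(abs(diff(sign(diff(stats::runmed(r_sin, 5))))) > 0)
  expect_gte(turns, 2)

  expect_error(whistle_synth_spec("upsweep", 300, c(9, 5)), "anchor")
  expect_error(whistle_synth_spec("concave", 300, c(5, 8, 5)), "anchor")
})

test_that("snaps are short, high-centroid, correctly scaled impulses", {
  for (tau in c(3, 5, 8)) {
    expect_lt(measure_click(make_snap(fs, 150, tau)$waveform, fs)$duration_us,
              15)
  }
  snap <- make_snap(fs, level_db = 150, tau_us = 5)
  m <- measure_click(snap$waveform, fs)
  expect_lt(abs(m$splpp_db - 150), 0.1)
  snap_centroid <- click_features(snap$waveform, fs)[["centroid_khz"]]
  # vs a population of default clicks across the carrier range
  set.seed(17)
  carriers <- sousawave:::r_truncnorm(20, 86.4, 19.5, 20)
  click_centroids <- vapply(carriers, function(fc) {
    p <- make_click_pulse(click_synth_spec(min(fc, 240), 8, splpp_db = 150),
                          fs)
    click_features(p$waveform, fs)[["centroid_khz"]]
  }, 0)
  expect_true(all(snap_centroid > click_centroids))
})

test_that("scenes are calibrated, annotated and seed-deterministic", {
  cfg0 <- scene_config(duration_s = 0.5, ambient_spl_db = 90, seed = 3L)
  sc0 <- render_scene(cfg0)
  expect_equal(nrow(sc0$annotation), 0L)
  expect_lt(abs(20 * log10(sqrt(mean(sc0$segment$samples^2))) - 90), 0.5)

  specs <- lapply(seq(0.05, 0.5, by = 0.05), function(t)
    click_synth_spec(86, 5, splpp_db = 150, onset_s = t))
  cfg <- scene_config(duration_s = 0.6, click_specs = specs, seed = 9L)
  sc <- render_scene(cfg)
  expect_equal(sum(sc$annotation$event_class == "click"), 10L)
  expect_true(!is.unsorted(sc$annotation$onset_s))

  sc2 <- render_scene(cfg)
  expect_identical(sc$segment$samples, sc2$segment$samples)
  f1 <- tempfile(fileext = ".wav")
  f2 <- tempfile(fileext = ".wav")
  write_wav(sc$segment, f1)
  write_wav(sc2$segment, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  file.remove(f1, f2)
})

test_that("writing a clipping scene names the overload", {
  # 200 dB pp exceeds full scale under the default calibration
  cfg <- scene_config(duration_s = 0.02, ambient_spl_db = 60,
                      click_specs = list(click_synth_spec(86, 5,
                                                          splpp_db = 200,
                                                          onset_s = 0.01)),
                      seed = 1L)
  sc <- render_scene(cfg)
  expect_error(write_wav(sc$segment, tempfile(fileext = ".wav")),
               "full scale")
})
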