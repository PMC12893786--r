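fs <- 576000

test_that("the energy operator matches its defining arithmetic", {
  expect_equal(tkeo(rep(3, 10)), numeric(10))
  expect_equal(tkeo(c(0, 1, 2, 1, 0)), c(0, 1, 3, 1, 0))
  x <- sin(2 * pi * (0:999) / 4)            # tone at fs/4
  expect_true(all(abs(tkeo(x)[2:999] - 1) < 1e-12))
  expect_error(tkeo(c(1, 2)), "at least 3")
  # quadratic scale law
  set.seed(8)
  y <- rnorm(100)
  expect_equal(tkeo(3 * y), 9 * tkeo(y))
})

test_that("smoothing kernels are matched-gain with the stated shape", {
  ker <- build_kernels(detector_config(), fs)
  expect_identical(length(ker$gaussian), length(ker$rect))
  expect_identical(length(ker$gaussian), 2L * ker$N + 1L)
  expect_equal(sum(ker$gaussian), sum(ker$rect))
  centre <- ker$gaussian[ker$N + 1L]
  half_tap <- ker$gaussian[ker$N + 1L + 29L]   # FWHM/2 = 28.8 -> 29 samples
  expect_lt(abs(half_tap / centre - 0.5), 0.03 * 0.5 + 0.02)
})

test_that("the filter difference ratio behaves as an impulse contrast", {
  ker <- build_kernels(detector_config(), fs)
  e <- numeric(4000)
  e[2000] <- 1
  fdr <- fdr_series(e, ker)
  expect_equal(fdr[2000],
               1 - mean(ker$gaussian) / max(ker$gaussian),
               tolerance = 1e-9)
  # stationary noise: equal-gain kernels pull the mean ratio to zero
  set.seed(41)
  fdr_noise <- fdr_series(tkeo(rnorm(300000)), ker)
  expect_lt(abs(mean(fdr_noise)), 0.05)
  # all-zero energy stays zero (h1 = 0 guard)
  expect_equal(fdr_series(numeric(1000), ker), numeric(1000))
  # scale invariance: the ratio of equal-gain filters ignores amplitude
  set.seed(42)
  e2 <- tkeo(rnorm(20000))
  expect_equal(fdr_series(25 * e2, ker), fdr_series(e2, ker),
               tolerance = 1e-9)
})

test_that("candidate extraction finds, merges and times transients", {
  expect_length(detect_candidates(audio_segment(numeric(10000), fs)), 0L)

  # two impulses 0.3 ms apart merge under the 1 ms refractory
  x <- numeric(20000)
  x[10000] <- 1
  x[10000 + round(0.3e-3 * fs)] <- 1
  expect_length(detect_candidates(audio_segment(x, fs)), 1L)

  onsets <- seq(0.1, 1.9, by = 0.2)
  cfg <- scene_config(duration_s = 2,
                      click_specs = lapply(onsets, function(t)
                        click_synth_spec(86, 8, splpp_db = 160,
                                         onset_s = t)),
                      ambient_spl_db = 95, seed = 13L)
  scene <- render_scene(cfg)
  cands <- detect_candidates(highpass(scene$segment))
  expect_length(cands, 10L)
  times <- vapply(cands, function(cd) cd$peak_time_s, 0)
  expect_true(all(abs(sort(times) - onsets) < 0.2e-3))
})

test_that("click windows grow from the peak and respect neighbours", {
  pulse <- make_click_pulse(click_synth_spec(90, 5, splpp_db = 150), fs)
  x <- numeric(4000)
  x[2000 - pulse$peak_index + seq_along(pulse$waveform)] <- pulse$waveform
  w <- extract_click_window(x, 2000L, fs)
  len_us <- length(w$window) / fs * 1e6
  expect_gte(len_us, 40)
  expect_lte(len_us, 120)
  expect_false(w$truncated)

  w_edge <- extract_click_window(c(0, 0, 1, 0, 0), 3L, fs)
  expect_true(w_edge$truncated)

  # two clicks 1 ms apart: each window excludes the other's peak
  gap <- round(1e-3 * fs)
  x2 <- numeric(6000)
  p1 <- 2000L
  p2 <- p1 + gap
  x2[p1 - pulse$peak_index + seq_along(pulse$waveform)] <- pulse$waveform
  x2[p2 - pulse$peak_index + seq_along(pulse$waveform)] <-
    x2[p2 - pulse$peak_index + seq_along(pulse$waveform)] + pulse$waveform
  w1 <- extract_click_window(x2, p1, fs)
  w2 <- extract_click_window(x2, p2, fs)
  expect_lt(w1$start_index + length(w1$window) - 1L, p2)
  expect_gt(w2$start_index, p1)
})

test_that("window features separate snaps from clicks and ignore level", {
  click <- make_click_pulse(click_synth_spec(86, 8, splpp_db = 150), fs)
  snap <- make_snap(fs, level_db = 150, tau_us = 5)
  fc <- click_features(click$waveform, fs)
  fsn <- click_features(snap$waveform, fs)
  expect_gt(fsn[["centroid_khz"]], fc[["centroid_khz"]])
  expect_equal(click_features(10 * click$waveform, fs), fc,
               tolerance = 1e-9)
  expect_error(click_features(numeric(50), fs), "all-zero")
})

test_that("the pluggable classifier separates synthetic classes", {
  clf <- default_classifier()
  # held-out scene, labels from ground truth
  held <- render_scene(standard_scene(duration_s = 20, n_clicks = 25L,
                                      snap_rate = 2, seed = 55L))
  seg <- highpass(held$segment)
  cands <- detect_candidates(seg)
  truth <- sousawave:::label_candidates_from_truth(cands, held$annotation)
  scored <- classify_candidates(cands, clf, fs)
  pred <- vapply(scored, function(cd) cd$label, "")
  expect_gte(mean(pred == truth), 0.95)

  # any scorer function can stand in
  stub <- classify_candidates(cands, function(f) 1, fs)
  expect_true(all(vapply(stub, function(cd) cd$label, "") == "click"))

  # a single-class training set is refused
  only_clicks <- standard_scene(duration_s = 3, n_clicks = 10L,
                                snap_rate = 0, seed = 77L)
  expect_error(train_click_classifier(list(only_clicks)), "both classes")
})
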