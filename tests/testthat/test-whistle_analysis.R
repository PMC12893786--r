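fs <- 576000

test_that("the spectrogram has the stated geometry and log scaling", {
  x <- sin(2 * pi * 6000 * (0:99999) / fs)
  sp <- spectrogram(x, fs)
  expect_equal(sp$bin_width_hz, 562.5)
  peaks <- apply(sp$values, 2L, which.max)
  expect_true(all(peaks == round(6000 / 562.5) + 1L))  # 0-based bin 11

  silent <- spectrogram(numeric(5000), fs)
  expect_true(all(silent$values == -120))

  sp10 <- spectrogram(10 * x, fs)
  above <- sp$values > -119 & sp10$values > -119  # floor masks the rest
  expect_equal(sp10$values[above], sp$values[above] + 20, tolerance = 1e-9)
  expect_gt(sum(above), 1000)

  expect_error(spectrogram(numeric(500), fs), "shorter")
})

test_that("enhancement removes speckle and preserves ordering", {
  sp <- spectrogram(numeric(600000), fs)
  sp$values <- matrix(5, 60, 80)
  e <- enhance(sp)
  expect_true(all(abs(e$values) < 1e-9))    # mean cancels a constant field

  set.seed(4)
  sp$values <- matrix(rnorm(60 * 80), 60, 80)
  sp$values[30, 40] <- 50                    # isolated speckle pixel
  e2 <- enhance(sp)
  offset <- 3 * sd(sp$values) - mean(sp$values)
  expect_lt(e2$values[30, 40] - offset, 4)   # the median removed the spike

  med <- sousawave:::median_filter_3x3(sp$values)
  expect_equal(cor(as.vector(e2$values), as.vector(med),
                   method = "spearman"), 1)
})

test_that("adaptive thresholding keeps lines and drops flat fields", {
  sp <- spectrogram(numeric(600000), fs)
  sp$values <- matrix(7, 64, 64)
  expect_false(any(adaptive_threshold(sp)))

  sp$values <- matrix(0, 64, 64)
  sp$values[32, ] <- 30                      # bright horizontal line
  mask <- adaptive_threshold(sp)
  expect_true(all(mask[32, ]))
  expect_false(any(mask[1:10, ]))
})

test_that("region filters apply the width and intensity rules", {
  sp <- spectrogram(numeric(600000), fs)
  sp$values <- matrix(0, 40, 60)
  mask <- matrix(FALSE, 40, 60)
  mask[10, 5:14] <- TRUE                     # width 10: dropped
  mask[25, 20:49] <- TRUE                    # width 30: kept
  sp$values[25, 20:49] <- 12
  regions <- extract_regions(mask, sp)
  expect_length(regions, 1L)
  expect_equal(regions[[1L]]$width, 30L)
  expect_equal(attr(regions, "n_dropped_width"), 1L)

  sp$values[25, 20:49] <- 9.5                # bright enough? no
  expect_length(extract_regions(mask, sp), 0L)

  # diagonal touching blobs are one region under 8-connectivity
  mask2 <- matrix(FALSE, 30, 40)
  mask2[10, 5:16] <- TRUE
  mask2[11, 17:28] <- TRUE                   # touches only diagonally
  sp$values <- matrix(15, 30, 40)
  regions2 <- extract_regions(mask2, sp)
  expect_length(regions2, 1L)
  expect_equal(regions2[[1L]]$width, 24L)
})

test_that("ridges track tones within quantization and interpolate gaps", {
  seg <- clean_tone_segment(whistle_synth_spec("constant", 300, 6))
  dw <- detect_whistles(seg)
  ct <- match_contour(dw$contours, 6, 0.05, 0.35)
  expect_false(is.null(ct))
  expect_true(all(abs(ct$freq_khz - 6.0) < 0.28))

  seg_up <- clean_tone_segment(whistle_synth_spec("upsweep", 300, c(5, 9)))
  dw_up <- detect_whistles(seg_up)
  ct_up <- match_contour(dw_up$contours, 7, 0.05, 0.35, f_tol_khz = 2.5)
  expect_false(is.null(ct_up))
  expect_true(all(diff(ct_up$freq_khz) > -0.15))

  # a hand-built region with a missing interior column is interpolated
  sp <- spectrogram(numeric(600000), fs)
  sp$values <- matrix(0, 40, 30)
  cols <- setdiff(5:20, 12L)
  sp$values[15, cols] <- 20
  k <- 15L + (cols - 1L) * 40L
  region <- list(pixels = k, rows = rep(15L, length(cols)), cols = cols,
                 width = 16L, max_value = 20)
  ct_gap <- ridge_contour(region, sp)
  expect_true(any(ct_gap$interpolated))
  expect_length(ct_gap$freq_khz, 16L)
})

test_that("contour metrics follow the generating archetypes", {
  seg <- clean_tone_segment(whistle_synth_spec("constant", 300, 6))
  ct <- match_contour(detect_whistles(seg)$contours, 6, 0.05, 0.35)
  m <- ct$metrics
  expect_lt(abs(m$duration_ms - 300), 2)
  expect_lt(abs(m$bf_khz - 6), 0.1)
  expect_lt(abs(m$ef_khz - 6), 0.1)
  expect_lt(m$range_khz, 0.1)
  expect_equal(ct$shape, "constant")

  seg_up <- clean_tone_segment(whistle_synth_spec("upsweep", 300, c(5, 9)))
  ct_up <- match_contour(detect_whistles(seg_up)$contours, 7, 0.05, 0.35,
                         f_tol_khz = 2.5)
  expect_lt(abs(ct_up$metrics$bf_khz - 5), 0.3)
  expect_lt(abs(ct_up$metrics$ef_khz - 9), 0.3)
  expect_lt(abs(ct_up$metrics$range_khz - 4), 0.5)
  expect_equal(ct_up$shape, "upsweep")

  seg_cx <- clean_tone_segment(whistle_synth_spec("convex", 300, c(5, 8, 5)))
  ct_cx <- match_contour(detect_whistles(seg_cx)$contours, 6.5, 0.05, 0.35,
                         f_tol_khz = 2.5)
  expect_lt(abs(ct_cx$metrics$maxf_khz - 8), 0.4)
  interior <- which.max(ct_cx$freq_khz)
  expect_gt(interior, 1L)
  expect_lt(interior, length(ct_cx$freq_khz))
  expect_equal(ct_cx$shape, "convex")

  expect_error(measure_whistle(structure(list(freq_khz = 5),
                                         class = "whistle_contour")),
               "at least 2")
})

test_that("a noisy tone is recovered end-to-end within tolerance", {
  seg <- noisy_tone_segment(whistle_synth_spec("constant", 300, 6), 20, 91)
  dw <- detect_whistles(seg)
  ct <- match_contour(dw$contours, 6, 0.06, 0.36)
  expect_false(is.null(ct))
  expect_lt(abs(ct$metrics$duration_ms - 300), 5)
  expect_lt(abs(ct$metrics$minf_khz - 6), 0.3)
  expect_lt(abs(ct$metrics$maxf_khz - 6), 0.3)
  # no reported whistle can be narrower than the width rule allows
  expect_true(all(dw$summary$duration_ms >=
                    (11 - 1) * 512 / fs * 1000 - 1e-9))
})
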