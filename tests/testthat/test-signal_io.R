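fs <- 576000

test_that("WAV round-trips preserve samples", {
  cal <- calibration()
  set.seed(2)
  seg <- audio_segment(rnorm(5000) * 1e4, 48000, calibration = cal)
  f1 <- tempfile(fileext = ".wav")
  f2 <- tempfile(fileext = ".wav")
  write_wav(seg, f1, "float32")
  back <- read_wav(f1, cal)
  expect_equal(back$sample_rate, 48000)
  write_wav(back, f2, "float32")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  write_wav(seg, f1, "pcm24")
  back24 <- read_wav(f1, cal)
  expect_lt(max(abs(back24$samples - seg$samples)),
            sousawave:::upa_per_unit(cal) / 2^22)
  write_wav(seg, f1, "pcm16")
  back16 <- read_wav(f1, cal)
  expect_lt(max(abs(back16$samples - seg$samples)),
            sousawave:::upa_per_unit(cal) / 2^14)
  file.remove(f1, f2)
})

test_that("calibration maps full-scale counts to the expected pressure", {
  cal <- calibration(sensitivity_db = -176, gain_db = 0, adc_full_scale = 1)
  f <- tempfile(fileext = ".wav")
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + 2L, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")      # PCM
  writeBin(1L, con, size = 2L, endian = "little")      # mono
  writeBin(48000L, con, size = 4L, endian = "little")
  writeBin(96000L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(2L, con, size = 4L, endian = "little")
  writeBin(-32768L, con, size = 2L, endian = "little") # negative full scale
  close(con)
  seg <- read_wav(f, cal)
  expect_equal(seg$samples, -1 * 10^(176 / 20))
  file.remove(f)
})

test_that("multichannel WAV files are rejected", {
  f <- tempfile(fileext = ".wav")
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + 4L, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")      # stereo
  writeBin(48000L, con, size = 4L, endian = "little")
  writeBin(192000L, con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(4L, con, size = 4L, endian = "little")
  writeBin(c(0L, 0L), con, size = 2L, endian = "little")
  close(con)
  expect_error(read_wav(f), "mono")
  file.remove(f)
})

test_that("high-pass filtering is sharp at 5 kHz and zero-phase", {
  n <- fs / 2
  tone <- function(f) audio_segment(sin(2 * pi * f * (0:n) / fs), fs)
  core <- 20000:260000   # avoid edge transients when comparing RMS
  r1k <- highpass(tone(1000))
  expect_lt(sqrt(mean(r1k$samples[core]^2)) /
              sqrt(mean(tone(1000)$samples[core]^2)), 0.01)
  r80k <- highpass(tone(80000))
  expect_lt(abs(sqrt(mean(r80k$samples[core]^2)) /
                  sqrt(mean(tone(80000)$samples[core]^2)) - 1), 0.01)
  z <- highpass(audio_segment(numeric(5000), fs))
  expect_equal(z$samples, numeric(5000))

  # a high-frequency transient keeps its timing exactly
  x <- numeric(20000)
  pulse <- make_click_pulse(click_synth_spec(90, 5, splpp_db = 120), fs)
  x[9000 + seq_along(pulse$waveform)] <- pulse$waveform
  xf <- highpass(audio_segment(x, fs))$samples
  cc <- stats::ccf(xf, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(highpass(tone(1000), cutoff_hz = fs), "Nyquist")
})

test_that("framing covers the stream with the stated geometry", {
  seg_of <- function(L) audio_segment(seq_len(L) * 1.0, fs)
  f1 <- frame_stream(seg_of(65792))
  expect_length(f1, 1L)
  expect_false(f1[[1L]]$partial)

  f2 <- frame_stream(seg_of(117760))
  expect_length(f2, 2L)
  expect_equal(f2[[2L]]$start_index, 51969L)  # sample 51968, 0-based
  expect_false(f2[[2L]]$partial)

  f3 <- frame_stream(seg_of(1000))
  expect_length(f3, 1L)
  expect_true(f3[[1L]]$partial)

  # every sample covered, none fabricated
  for (L in c(1000, 65792, 100000, 130000)) {
    fr <- frame_stream(seg_of(L))
    covered <- sort(unique(unlist(lapply(fr, function(f)
      f$start_index + seq_along(f$samples) - 1L))))
    expect_identical(covered, seq_len(L))
    expect_true(all(unlist(lapply(fr, function(f) f$samples)) <= L))
  }
})

test_that("region assignment uses the inclusive disjoint boxes", {
  expect_equal(assign_region(24.40, 118.00), "West")
  expect_equal(assign_region(24.50, 118.30), "East")
  expect_equal(assign_region(24.50, 118.18), "unassigned")
  expect_equal(assign_region(24.57, 118.16), "West")   # inclusive corner
  b <- sousawave:::region_boxes
  expect_lt(b$West$lon[2], b$East$lon[1])              # longitude-disjoint
})
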