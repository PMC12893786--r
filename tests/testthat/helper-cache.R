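# Expensive fixtures (rendered scenes, the trained classifier) are built
# once per test run and shared across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- force(expr)
  }
  .fixture_cache[[name]]
}

default_classifier <- function() {
  cached("classifier", train_click_classifier(training_scene_configs()))
}

standard_scene_rendered <- function() {
  cached("scene7", {
    scene <- render_scene(standard_scene())
    scene$highpassed <- highpass(scene$segment)
    scene
  })
}

# A clean (noise-free) tone embedded in silence, for by-construction
# whistle checks.
clean_tone_segment <- function(spec, pad_s = 0.05, sample_rate = 576000) {
  tone <- make_whistle_waveform(spec, sample_rate)
  pad <- round(pad_s * sample_rate)
  x <- numeric(length(tone$waveform) + 2L * pad)
  x[pad + seq_along(tone$waveform)] <- tone$waveform * 1e6
  audio_segment(x, sample_rate)
}

# A tone in Gaussian ambient noise at a given RMS SNR.
noisy_tone_segment <- function(spec, snr_db, seed, pad_s = 0.06,
                               ambient_spl_db = 95, sample_rate = 576000) {
  tone <- make_whistle_waveform(spec, sample_rate)
  amb <- 10^(ambient_spl_db / 20)
  pad <- round(pad_s * sample_rate)
  set.seed(seed)
  x <- rnorm(length(tone$waveform) + 2L * pad) * amb
  idx <- pad + seq_along(tone$waveform)
  x[idx] <- x[idx] + sqrt(2) * amb * 10^(snr_db / 20) * tone$waveform
  audio_segment(x, sample_rate)
}
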