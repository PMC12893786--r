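# Parameter-recovery harnesses: embed synthetic events with known
# parameters in calibrated noise, run the full detection + measurement
# pipelines, and return drawn-versus-measured tables.  These drive both
# the validation suite and the reproduction script.

# RMS of a pulse over its 95%-energy support (envelope-based), the
# reference level for the RMS signal-to-noise ratio used when embedding
# events in ambient noise.
pulse_rms95 <- function(waveform, sample_rate) {
  dur <- energy_duration(envelope(waveform), sample_rate)$duration
  sqrt(0.95 * sum(waveform^2) / sample_rate / dur)
}

#' Click parameter-recovery simulation
#'
#' Draws `n` click parameters from the reference population
#' distributions, synthesizes one chirped-Gabor click per draw, embeds it
#' in Gaussian ambient noise at the requested RMS SNR, and runs the full
#' chain: 5 kHz high-pass, TKEO/FDR detection (FWHM 0.10 ms, threshold
#' 0.7), peak-referenced window extraction and spectral measurement.
#'
#' The varied parameter determines the generator: `"peak_frequency"`
#' draws the carrier (truncated normal, sigma fixed at 5 us);
#' `"bw3"` draws the -3 dB bandwidth and sets the envelope sigma via the
#' closed form `sigma = sqrt(ln 2) / (pi BW)` at an 86 kHz carrier;
#' `"duration"` draws the 95%-energy duration and sets
#' `sigma = duration / 2.772`; `"splpp"` draws the peak-to-peak level.
#'
#' @param n number of synthetic clicks.
#' @param parameter which Table-style parameter to vary and recover.
#' @param seed RNG seed.
#' @param snr_db embedding RMS SNR (event RMS over its 95%-energy support
#'   relative to ambient RMS), dB.
#' @param sample_rate sampling rate, Hz.
#' @param pop population statistics, see [click_population_defaults].
#' @return A data frame with columns `drawn`, `measured` (NA where the
#'   detector produced no candidate) and `detected`.
#' @export
simulate_click_recovery <- function(n,
                                    parameter = c("peak_frequency", "bw3",
                                                  "duration", "splpp"),
                                    seed = 1L, snr_db = 25,
                                    sample_rate = 576000,
                                    pop = click_population_defaults) {
  parameter <- match.arg(parameter)
  cfg <- detector_config()
  bf <- signal::butter(4, 5000 / (sample_rate / 2), type = "high")
  pad <- round(1.5e-3 * sample_rate)
  with_seed(seed, {
    drawn <- switch(parameter,
      peak_frequency = {
        p <- pop$peak_frequency_khz
        r_truncnorm(n, p$mean, p$sd, p$floor)
      },
      bw3 = {
        p <- pop$bw3_khz
        r_truncnorm(n, p$mean, p$sd, p$floor)
      },
      duration = {
        p <- pop$duration_us
        r_truncnorm(n, p$mean, p$sd, p$floor)
      },
      splpp = {
        p <- pop$splpp_db
        stats::rnorm(n, p$mean, p$sd)
      })
    measured <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      spec <- switch(parameter,
        peak_frequency = click_synth_spec(carrier_khz = drawn[i],
                                          sigma_us = 5, splpp_db = 160),
        bw3 = click_synth_spec(carrier_khz = 86,
                               sigma_us = sqrt(log(2)) /
                                 (pi * drawn[i] * 1000) * 1e6,
                               splpp_db = 160),
        duration = click_synth_spec(carrier_khz = 86,
                                    sigma_us = drawn[i] / 2.772,
                                    splpp_db = 160),
        splpp = click_synth_spec(carrier_khz = 86, sigma_us = 5,
                                 splpp_db = drawn[i]))
      pulse <- make_click_pulse(spec, sample_rate)
      noise_sd <- pulse_rms95(pulse$waveform, sample_rate) / from_dB(snr_db)
      len <- length(pulse$waveform) + 2L * pad
      x <- stats::rnorm(len) * noise_sd
      idx <- pad + seq_along(pulse$waveform)
      x[idx] <- x[idx] + pulse$waveform
      seg <- audio_segment(zero_phase_filter(bf, x), sample_rate)
      cands <- detect_candidates(seg, cfg)
      if (length(cands) == 0L) next
      centre <- pad + pulse$peak_index
      best <- which.min(vapply(cands, function(cd)
        abs(cd$peak_index - centre), 0))
      if (abs(cands[[best]]$peak_index - centre) > 0.5e-3 * sample_rate) next
      m <- measure_click(cands[[best]]$window, sample_rate)
      measured[i] <- switch(parameter, peak_frequency = m$fp_khz,
                            bw3 = m$bw3_khz, duration = m$duration_us,
                            splpp = m$splpp_db)
    }
    data.frame(drawn = drawn, measured = measured,
               detected = !is.na(measured))
  })
}

#' Whistle parameter-recovery simulation
#'
#' Draws `n` whistle parameters from the reference lognormal
#' distributions, synthesizes one constant-frequency tone per draw,
#' embeds it in Gaussian ambient noise at the requested RMS SNR, and runs
#' the whistle pipeline (hop 512, radius 15, min width 11, min peak 10).
#' The recovered contour is the one overlapping the true tone in time
#' and frequency; its metric of interest is returned.
#'
#' `"duration"` draws the duration (tone at 6 kHz); `"minf"` and
#' `"maxf"` draw the tone frequency (300 ms tones) and recover the
#' contour's minimum / maximum frequency.
#'
#' @param n number of synthetic whistles.
#' @param parameter which parameter to vary and recover.
#' @param seed RNG seed.
#' @param snr_db embedding RMS SNR, dB.
#' @param sample_rate sampling rate, Hz.
#' @param ambient_spl_db ambient noise level, dB re 1 uPa.
#' @param pop population statistics, see [whistle_population_defaults].
#' @return A data frame with columns `drawn`, `measured`, `detected`.
#' @export
simulate_whistle_recovery <- function(n,
                                      parameter = c("duration", "minf",
                                                    "maxf"),
                                      seed = 1L, snr_db = 20,
                                      sample_rate = 576000,
                                      ambient_spl_db = 95,
                                      pop = whistle_population_defaults) {
  parameter <- match.arg(parameter)
  pad_s <- 0.06
  amb <- from_dB(ambient_spl_db)
  with_seed(seed, {
    drawn <- switch(parameter,
      duration = r_lognormal_ms(n, pop$duration_ms$mean, pop$duration_ms$sd),
      minf = r_lognormal_ms(n, pop$minf_khz$mean, pop$minf_khz$sd),
      maxf = r_lognormal_ms(n, pop$maxf_khz$mean, pop$maxf_khz$sd))
    measured <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      dur_ms <- if (parameter == "duration") drawn[i] else 300
      f_khz <- if (parameter == "duration") 6 else drawn[i]
      spec <- whistle_synth_spec("constant", dur_ms, f_khz,
                                 snr_db = snr_db, onset_s = pad_s)
      tone <- make_whistle_waveform(spec, sample_rate)
      len <- length(tone$waveform) + 2L * round(pad_s * sample_rate)
      x <- stats::rnorm(len) * amb
      amp <- sqrt(2) * amb * from_dB(snr_db)
      idx <- round(pad_s * sample_rate) + seq_along(tone$waveform)
      x[idx] <- x[idx] + amp * tone$waveform
      dw <- detect_whistles(audio_segment(x, sample_rate))
      ct <- match_contour(dw$contours, f_khz, pad_s,
                          pad_s + dur_ms / 1000)
      if (is.null(ct)) next
      measured[i] <- switch(parameter,
                            duration = ct$metrics$duration_ms,
                            minf = ct$metrics$minf_khz,
                            maxf = ct$metrics$maxf_khz)
    }
    data.frame(drawn = drawn, measured = measured,
               detected = !is.na(measured))
  })
}

#' Match a detected contour to an annotated tonal event
#'
#' Among contours whose median ridge frequency lies within `f_tol_khz` of
#' the true frequency, returns the one with the largest time overlap with
#' the annotated interval, or `NULL` when none overlaps.
#'
#' @param contours contour list from [detect_whistles()].
#' @param freq_khz true (e.g. annotated) tone frequency, kHz.
#' @param onset_s,offset_s annotated event interval, seconds.
#' @param f_tol_khz frequency matching tolerance, kHz.
#' @return A `whistle_contour` or `NULL`.
#' @export
match_contour <- function(contours, freq_khz, onset_s, offset_s,
                          f_tol_khz = 1.5) {
  best <- NULL
  best_ov <- 0
  for (ct in contours) {
    if (abs(stats::median(ct$freq_khz) - freq_khz) > f_tol_khz) next
    t0 <- ct$times_s[1L]
    t1 <- ct$times_s[length(ct$times_s)]
    ov <- min(t1, offset_s) - max(t0, onset_s)
    if (ov > best_ov) {
      best_ov <- ov
      best <- ct
    }
  }
  best
}

#' Shape-archetype classification trials
#'
#' Generates whistles of the six contour archetypes with randomized
#' anchors and durations, embeds each in ambient noise, runs the whistle
#' pipeline and compares the classified shape against the generating
#' archetype.
#'
#' @param n_trials total number of trials (cycled over the six types).
#' @param seed RNG seed.
#' @param snr_db embedding RMS SNR, dB.
#' @param sample_rate sampling rate, Hz.
#' @return A data frame with `true_shape`, `detected_shape` (NA when no
#'   contour was recovered) and `correct`.
#' @export
simulate_shape_trials <- function(n_trials = 300L, seed = 1L, snr_db = 15,
                                  sample_rate = 576000) {
  types <- c("constant", "upsweep", "downsweep", "concave", "convex",
             "sinusoidal")
  pad_s <- 0.06
  amb <- from_dB(95)
  with_seed(seed, {
    true_shape <- rep(types, length.out = n_trials)
    detected <- rep(NA_character_, n_trials)
    for (i in seq_len(n_trials)) {
      base <- stats::runif(1, 4, 9)
      span <- stats::runif(1, 2, 4)
      anchors <- switch(true_shape[i],
        constant = base,
        upsweep = c(base, base + span),
        downsweep = c(base + span, base),
        concave = c(base + span, base, base + stats::runif(1, 0.6, 1) * span),
        convex = c(base, base + span, base + stats::runif(1, 0, 0.4) * span),
        sinusoidal = base + span * c(0, 1, 0, 1))
      dur_ms <- stats::runif(1, 250, 450)
      spec <- whistle_synth_spec(true_shape[i], dur_ms, anchors,
                                 snr_db = snr_db, onset_s = pad_s)
      tone <- make_whistle_waveform(spec, sample_rate)
      len <- length(tone$waveform) + 2L * round(pad_s * sample_rate)
      x <- stats::rnorm(len) * amb
      amp <- sqrt(2) * amb * from_dB(snr_db)
      idx <- round(pad_s * sample_rate) + seq_along(tone$waveform)
      x[idx] <- x[idx] + amp * tone$waveform
      dw <- detect_whistles(audio_segment(x, sample_rate))
      ct <- match_contour(dw$contours, mean(anchors), pad_s,
                          pad_s + dur_ms / 1000, f_tol_khz = span + 1.5)
      if (!is.null(ct)) detected[i] <- ct$shape
    }
    data.frame(true_shape = true_shape, detected_shape = detected,
               correct = !is.na(detected) & detected == true_shape,
               stringsAsFactors = FALSE)
  })
}

#' The standard seeded detector-validation scene
#'
#' A 60 s, 576 kHz scene with 50 well-separated clicks at 160 dB
#' peak-to-peak (carriers and durations drawn from the reference click
#' population), ambient noise at 95 dB re 1 uPa and snapping-shrimp
#' impulses at 1 event/s, seed 7 -- the fixture for the end-to-end
#' detector precision/recall check.
#'
#' @param duration_s scene length, s.
#' @param n_clicks number of clicks.
#' @param splpp_db click peak-to-peak level, dB re 1 uPa.
#' @param ambient_spl_db ambient level, dB re 1 uPa.
#' @param snap_rate snap rate, events/s.
#' @param seed scene seed.
#' @return A [scene_config()].
#' @export
standard_scene <- function(duration_s = 60, n_clicks = 50L,
                           splpp_db = 160, ambient_spl_db = 95,
                           snap_rate = 1, seed = 7L) {
  specs <- with_seed(seed + 1000L, {
    repeat {
      onsets <- sort(stats::runif(n_clicks, 0.2, duration_s - 0.2))
      if (n_clicks < 2L || min(diff(onsets)) > 0.02) break
    }
    carriers <- r_truncnorm(n_clicks, click_population_defaults$peak_frequency_khz$mean,
                            click_population_defaults$peak_frequency_khz$sd,
                            click_population_defaults$peak_frequency_khz$floor)
    durs <- r_truncnorm(n_clicks, click_population_defaults$duration_us$mean,
                        click_population_defaults$duration_us$sd,
                        click_population_defaults$duration_us$floor)
    lapply(seq_len(n_clicks), function(i)
      click_synth_spec(carrier_khz = min(carriers[i], 240),
                       sigma_us = durs[i] / 2.772,
                       splpp_db = splpp_db, onset_s = onsets[i]))
  })
  scene_config(duration_s = duration_s, ambient_spl_db = ambient_spl_db,
               snap_rate = snap_rate, click_specs = specs, seed = seed)
}

#' Training scenes for the click/non-click classifier
#'
#' Shorter scenes containing clicks over a range of levels plus a high
#' snap rate, giving the classifier balanced synthetic examples of both
#' classes.
#'
#' @param seeds integer vector; one scene per seed.
#' @param duration_s per-scene length, s.
#' @param n_clicks clicks per scene.
#' @return A list of [scene_config()] objects.
#' @export
training_scene_configs <- function(seeds = c(101L, 102L, 103L),
                                   duration_s = 15, n_clicks = 30L) {
  lapply(seeds, function(s) {
    cfg <- standard_scene(duration_s = duration_s, n_clicks = n_clicks,
                          snap_rate = 3, seed = s)
    with_seed(s + 5000L, {
      for (i in seq_along(cfg$click_specs)) {
        cfg$click_specs[[i]]$splpp_db <- stats::runif(1, 150, 175)
      }
    })
    cfg
  })
}
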