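# Spectral and temporal measurement of extracted click windows.

# Magnitude spectrum of a window zero-padded to >= 4096 points.
click_spectrum <- function(window, sample_rate, nfft_min = 4096L) {
  n <- length(window)
  nfft <- stats::nextn(max(nfft_min, n), 2L)
  S <- Mod(stats::fft(c(window, numeric(nfft - n))))
  nb <- nfft %/% 2L + 1L
  list(mag = S[seq_len(nb)],
       freq = (seq_len(nb) - 1L) * sample_rate / nfft)
}

# Width (Hz) of the contiguous interval around the peak bin where power
# stays within `drop_db` of the peak, with linear interpolation in dB at
# the two crossings.
bandwidth_at <- function(mag_db, freq, peak_bin, drop_db) {
  thr <- mag_db[peak_bin] - drop_db
  i <- peak_bin
  while (i > 1L && mag_db[i - 1L] >= thr) i <- i - 1L
  f_lo <- if (i == 1L) freq[1L] else {
    frac <- (mag_db[i] - thr) / (mag_db[i] - mag_db[i - 1L])
    freq[i] - frac * (freq[i] - freq[i - 1L])
  }
  j <- peak_bin
  nb <- length(mag_db)
  while (j < nb && mag_db[j + 1L] >= thr) j <- j + 1L
  f_hi <- if (j == nb) freq[nb] else {
    frac <- (mag_db[j] - thr) / (mag_db[j] - mag_db[j + 1L])
    freq[j] + frac * (freq[j + 1L] - freq[j])
  }
  f_hi - f_lo
}

# Central 95%-energy interval of a cumulative energy density, with
# linear interpolation between samples.  Returns times in seconds
# relative to the first sample.
energy_duration <- function(window, sample_rate, frac = 0.95) {
  e <- cumsum(window^2)
  total <- e[length(e)]
  if (total <= 0) stop("window has no energy")
  lo_t <- (1 - frac) / 2 * total
  hi_t <- (1 + frac) / 2 * total
  cross <- function(target) {
    i <- which(e >= target)[1L]
    if (i == 1L) return(0)
    prev <- e[i - 1L]
    (i - 2L + (target - prev) / (e[i] - prev)) / sample_rate
  }
  t_lo <- cross(lo_t)
  t_hi <- cross(hi_t)
  list(t_lo = t_lo, t_hi = t_hi, duration = t_hi - t_lo)
}

# Duration from the -10 dB points of the Hilbert envelope (alternative
# convention, selectable in measure_click()).
envelope_duration <- function(window, sample_rate, drop_db = 10) {
  env <- envelope(window)
  thr <- max(env) * from_dB(-drop_db)
  idx <- which(env >= thr)
  (max(idx) - min(idx)) / sample_rate
}

#' Measure the standard acoustic parameters of a click
#'
#' Computes peak frequency, -3/-6/-10 dB bandwidths (contiguous interval
#' around the spectral peak, linearly interpolated at the crossings),
#' duration and peak-to-peak sound pressure level from an extracted click
#' window.  The spectrum is taken on the window zero-padded to at least
#' 4096 points (about 141 Hz resolution at 576 kHz).
#'
#' @param window pressure waveform of the isolated click, uPa.
#' @param sample_rate sampling rate, Hz.
#' @param duration_method `"energy95"` (default): central 95%-energy
#'   interval of the cumulative squared Hilbert envelope (the envelope
#'   removes the carrier-phase ripple that otherwise biases the energy
#'   quantiles of near-single-cycle pulses); `"energy95_raw"`: the same
#'   quantiles on the raw squared pressure; `"env10db"`: -10 dB width of
#'   the Hilbert envelope.
#' @return An object of class `click_metrics`: a list with `fp_khz`,
#'   `bw3_khz`, `bw6_khz`, `bw10_khz`, `duration_us`, `splpp_db`.
#' @export
measure_click <- function(window, sample_rate,
                          duration_method = c("energy95", "energy95_raw",
                                              "env10db")) {
  duration_method <- match.arg(duration_method)
  stopifnot(is.numeric(window), length(window) >= 3L,
            is_number(sample_rate), sample_rate > 0)
  if (all(window == 0)) stop("cannot measure an all-zero window")
  sp <- click_spectrum(window, sample_rate)
  mag_db <- dB(pmax(sp$mag, .Machine$double.xmin))
  peak_bin <- which.max(mag_db)
  dur <- switch(duration_method,
    energy95 = {
      ef <- envelope_fine(window, sample_rate)
      energy_duration(ef$env, ef$sample_rate)$duration
    },
    energy95_raw = energy_duration(window, sample_rate)$duration,
    env10db = envelope_duration(window, sample_rate))
  structure(list(
    fp_khz = sp$freq[peak_bin] / 1000,
    bw3_khz = bandwidth_at(mag_db, sp$freq, peak_bin, 3) / 1000,
    bw6_khz = bandwidth_at(mag_db, sp$freq, peak_bin, 6) / 1000,
    bw10_khz = bandwidth_at(mag_db, sp$freq, peak_bin, 10) / 1000,
    duration_us = dur * 1e6,
    splpp_db = dB(max(window) - min(window))
  ), class = "click_metrics")
}

#' Summarize a batch of click (or whistle) metrics
#'
#' Per-parameter mean, standard deviation (n - 1 denominator), minimum and
#' maximum, in the conventional "mean +/- SD / range" reporting layout.
#' A single observation has its SD reported as 0 and flagged.
#'
#' @param metrics a list of `click_metrics` objects or a data frame of
#'   numeric measurement columns.
#' @return A data frame with columns `parameter`, `n`, `mean`, `sd`,
#'   `min`, `max`, `sd_defined`.
#' @export
summarize_metrics <- function(metrics) {
  if (is.data.frame(metrics)) {
    df <- metrics
  } else if (is.list(metrics) && length(metrics) > 0L) {
    df <- as.data.frame(do.call(rbind, lapply(metrics, function(m)
      unlist(m[vapply(m, is.numeric, TRUE)]))))
  } else {
    stop("metrics must be a non-empty list or data frame")
  }
  num <- vapply(df, is.numeric, TRUE)
  df <- df[, num, drop = FALSE]
  if (nrow(df) == 0L || ncol(df) == 0L) stop("no numeric measurements to summarize")
  out <- do.call(rbind, lapply(names(df), function(nm) {
    v <- df[[nm]]
    data.frame(parameter = nm, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               min = min(v), max = max(v),
               sd_defined = length(v) > 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Format a metrics summary in one-decimal reporting style
#'
#' @param summary data frame from [summarize_metrics()].
#' @return Character matrix with `Mean +/- SD` and `Range` columns.
#' @export
format_metrics_summary <- function(summary) {
  cbind(parameter = summary$parameter,
        `Mean +/- SD` = sprintf("%.1f ± %.1f", summary$mean, summary$sd),
        Range = sprintf("%.1f–%.1f", summary$min, summary$max))
}
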