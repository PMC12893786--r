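# Audio input/output, calibration and framing shared by both pipelines.

#' Hydrophone calibration chain
#'
#' Converts recorder counts to sound pressure.  A digitized sample at full
#' scale corresponds to `adc_full_scale` volts at the ADC; dividing by the
#' linear gain and the hydrophone sensitivity (dB re 1 V/uPa) yields
#' pressure in micropascal.
#'
#' @param sensitivity_db hydrophone sensitivity, dB re 1 V/uPa (typically
#'   around -176 for an autonomous recorder).
#' @param gain_db amplifier gain, dB.
#' @param adc_full_scale ADC full-scale voltage, V.
#' @return An object of class `calibration`.
#' @export
calibration <- function(sensitivity_db = -176, gain_db = 0,
                        adc_full_scale = 1) {
  stopifnot(is_number(sensitivity_db), is_number(gain_db),
            is_number(adc_full_scale), adc_full_scale > 0)
  structure(list(sensitivity_db = sensitivity_db, gain_db = gain_db,
                 adc_full_scale = adc_full_scale), class = "calibration")
}

# uPa per unit of normalized ([-1, 1]) sample amplitude.
upa_per_unit <- function(cal) {
  cal$adc_full_scale / from_dB(cal$sensitivity_db + cal$gain_db)
}

#' Calibrated pressure time series
#'
#' @param samples numeric vector of pressure values, uPa.
#' @param sample_rate sampling rate, Hz.
#' @param start_time time of the first sample, seconds.
#' @param site optional `c(lat, lon)` of the recording site, degrees.
#' @param region optional region label; if missing and `site` is given it
#'   is derived with [assign_region()].
#' @param calibration optional [calibration()] used to produce the samples.
#' @return An object of class `audio_segment`.
#' @export
audio_segment <- function(samples, sample_rate, start_time = 0,
                          site = NULL, region = NULL, calibration = NULL) {
  stopifnot(is.numeric(samples), is_number(sample_rate), sample_rate > 0,
            is_number(start_time))
  if (any(!is.finite(samples))) stop("samples must all be finite")
  if (is.null(region) && !is.null(site)) {
    region <- assign_region(site[1], site[2])
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 start_time = start_time, site = site,
                 region = if (is.null(region)) "unassigned" else region,
                 calibration = calibration),
            class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment> %d samples @ %g Hz (%.3f s), region %s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$region))
  invisible(x)
}

read_chunk_header <- function(con) {
  id <- rawToChar(readBin(con, "raw", 4L))
  size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  list(id = id, size = size)
}

#' Read a mono WAV file as a calibrated pressure series
#'
#' Supports PCM-16, PCM-24 and IEEE float-32 encodings, one channel only.
#' Sample values are converted counts -> volts -> micropascal through the
#' supplied calibration.
#'
#' @param path WAV file path.
#' @param cal a [calibration()].
#' @param site,region optional provenance passed to [audio_segment()].
#' @return An [audio_segment()].
#' @export
read_wav <- function(path, cal = calibration(), site = NULL, region = NULL) {
  stopifnot(inherits(cal, "calibration"))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- read_chunk_header(con)
  if (riff$id != "RIFF") stop("not a RIFF/WAVE file")
  if (rawToChar(readBin(con, "raw", 4L)) != "WAVE") stop("not a RIFF/WAVE file")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    hdr <- tryCatch(read_chunk_header(con), error = function(e) NULL)
    if (is.null(hdr) || length(hdr$size) == 0L || is.na(hdr$size)) break
    if (hdr$id == "fmt ") {
      raw <- readBin(con, "raw", hdr$size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1L, 2L, signed = FALSE,
                         endian = "little"),
        channels = readBin(raw[3:4], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little"))
    } else if (hdr$id == "data") {
      data_raw <- readBin(con, "raw", hdr$size)
    } else {
      seek(con, hdr$size + hdr$size %% 2L, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: missing fmt or data chunk")
  if (fmt$channels != 1L) stop("only mono WAV files are supported")
  norm <- if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3L)
    v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "numeric", length(data_raw) %/% 4L, size = 4L,
            endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                 fmt$format, fmt$bits))
  }
  pressure <- norm * upa_per_unit(cal)
  audio_segment(pressure, fmt$sample_rate, site = site, region = region,
                calibration = cal)
}

#' Write an audio segment as a mono WAV file
#'
#' The inverse of [read_wav()]: pressure is converted back to normalized
#' counts through the segment's (or supplied) calibration.  An event whose
#' pressure exceeds WAV full scale raises an error rather than clipping.
#'
#' @param segment an [audio_segment()].
#' @param path output file.
#' @param encoding `"float32"` (default), `"pcm16"` or `"pcm24"`.
#' @param cal calibration; defaults to the segment's, else [calibration()].
#' @return `path`, invisibly.
#' @export
write_wav <- function(segment, path, encoding = c("float32", "pcm16", "pcm24"),
                      cal = NULL) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(segment, "audio_segment"))
  if (is.null(cal)) cal <- segment$calibration
  if (is.null(cal)) cal <- calibration()
  norm <- segment$samples / upa_per_unit(cal)
  over <- which(abs(norm) > 1)
  if (length(over) > 0L) {
    stop(sprintf("pressure exceeds WAV full scale at %.4f s (|amp| = %.2f FS)",
                 (over[1] - 1L) / segment$sample_rate, max(abs(norm))))
  }
  fs <- as.integer(round(segment$sample_rate))
  n <- length(norm)
  fmt_code <- if (encoding == "float32") 3L else 1L
  bits <- switch(encoding, float32 = 32L, pcm16 = 16L, pcm24 = 24L)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(fs, con, size = 4L, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (encoding == "float32") {
    writeBin(norm, con, size = 4L, endian = "little")
  } else if (encoding == "pcm16") {
    writeBin(as.integer(round(pmax(pmin(norm, 1), -1) * 32767)), con,
             size = 2L, endian = "little")
  } else {
    v <- as.integer(round(pmax(pmin(norm, 1), -1) * 8388607))
    v <- ifelse(v < 0L, v + 16777216L, v)
    m <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    writeBin(as.raw(m), con)
  }
  invisible(path)
}

#' Zero-phase high-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth high-pass, used to
#' remove low-frequency ocean noise before click detection without
#' shifting click peaks in time.
#'
#' @param segment an [audio_segment()].
#' @param cutoff_hz cutoff frequency, Hz (default 5000; must be below
#'   Nyquist).
#' @return The filtered [audio_segment()].
#' @export
highpass <- function(segment, cutoff_hz = 5000) {
  stopifnot(inherits(segment, "audio_segment"), is_number(cutoff_hz))
  nyq <- segment$sample_rate / 2
  if (cutoff_hz >= nyq) stop("cutoff must be below Nyquist")
  bf <- signal::butter(4, cutoff_hz / nyq, type = "high")
  segment$samples <- zero_phase_filter(bf, segment$samples)
  segment
}

#' Framing specification
#'
#' @param frame_len frame length in samples (default 65792).
#' @param overlap overlap between adjacent frames in samples
#'   (default 13824); must satisfy `0 <= overlap < frame_len`.
#' @return An object of class `frame_spec`.
#' @export
frame_spec <- function(frame_len = 65792L, overlap = 13824L) {
  stopifnot(is_number(frame_len), frame_len >= 1,
            is_number(overlap), overlap >= 0, overlap < frame_len)
  structure(list(frame_len = as.integer(frame_len),
                 overlap = as.integer(overlap)), class = "frame_spec")
}

#' Split a segment into overlapping analysis frames
#'
#' Frames start at multiples of `frame_len - overlap`; a final partial
#' frame is retained and flagged rather than padded, so every sample is
#' covered and none is fabricated.
#'
#' @param segment an [audio_segment()].
#' @param spec a [frame_spec()].
#' @return A list of frames, each a list with `samples`, `start_index`
#'   (1-based sample index into the segment), `start_time` (s) and
#'   `partial` (logical).
#' @export
frame_stream <- function(segment, spec = frame_spec()) {
  stopifnot(inherits(segment, "audio_segment"), inherits(spec, "frame_spec"))
  L <- length(segment$samples)
  if (L < 1L) stop("segment is empty")
  step <- spec$frame_len - spec$overlap
  starts <- seq(1L, max(L - spec$overlap, 1L), by = step)
  lapply(starts, function(s) {
    e <- min(s + spec$frame_len - 1L, L)
    list(samples = segment$samples[s:e],
         start_index = s,
         start_time = segment$start_time + (s - 1L) / segment$sample_rate,
         partial = (e - s + 1L) < spec$frame_len)
  })
}

# Inclusive bounding boxes of the two study sub-regions (deg N, deg E).
region_boxes <- list(
  West = list(lat = c(24.30, 24.57), lon = c(117.94, 118.16)),
  East = list(lat = c(24.45, 24.63), lon = c(118.22, 118.50))
)

#' Assign a recording site to the West or East sub-region
#'
#' Inclusive bounding-box membership; the two boxes are disjoint in
#' longitude, and a site outside both is `"unassigned"` (and excluded from
#' group comparisons rather than guessed).
#'
#' @param lat latitude, degrees N.
#' @param lon longitude, degrees E.
#' @return `"West"`, `"East"` or `"unassigned"`.
#' @export
assign_region <- function(lat, lon) {
  stopifnot(is_number(lat), is_number(lon))
  for (nm in names(region_boxes)) {
    b <- region_boxes[[nm]]
    if (lat >= b$lat[1] && lat <= b$lat[2] &&
        lon >= b$lon[1] && lon <= b$lon[2]) {
      return(nm)
    }
  }
  "unassigned"
}
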