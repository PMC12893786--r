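# Whistle contour extraction: STFT spectrogram, median-filter
# enhancement with a global scalar offset, adaptive circular-neighborhood
# thresholding, 8-connected component filtering, ridge extraction,
# contour metrics and six-way shape classification.

#' Log-magnitude spectrogram
#'
#' Short-time Fourier transform with a 1024-sample Hanning window at the
#' given hop, as `P[m, f] = 20 log10 |STFT|`; zero-magnitude bins are
#' floored at -120 dB.
#'
#' @param samples pressure series (or an [audio_segment()]).
#' @param sample_rate sampling rate, Hz (ignored if `samples` is an
#'   `audio_segment`).
#' @param hop hop between columns, samples (default 512).
#' @param nfft window/FFT length, samples (default 1024).
#' @return An object of class `spectrogram`: a list with `values`
#'   (frequency-bin x time-column dB matrix), `freq_khz`, `times_s`,
#'   `hop`, `nfft`, `sample_rate`, `bin_width_hz`, `col_step_s`.
#' @export
spectrogram <- function(samples, sample_rate = NULL, hop = 512L,
                        nfft = 1024L) {
  if (inherits(samples, "audio_segment")) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples
  }
  stopifnot(is.numeric(samples), is_number(sample_rate), sample_rate > 0)
  n <- length(samples)
  if (n < nfft) stop("input shorter than one analysis window")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1L)) / (nfft - 1L))   # Hanning
  starts <- seq(1L, n - nfft + 1L, by = hop)
  frames <- matrix(samples[outer(0:(nfft - 1L), starts, `+`)], nrow = nfft)
  S <- stats::mvfft(frames * w)
  nb <- nfft %/% 2L + 1L
  mag <- Mod(S[seq_len(nb), , drop = FALSE])
  P <- dB(pmax(mag, 1e-6))
  P[P < -120] <- -120
  structure(list(values = P,
                 freq_khz = (seq_len(nb) - 1L) * sample_rate / nfft / 1000,
                 times_s = (starts - 1L + nfft / 2) / sample_rate,
                 hop = as.integer(hop), nfft = as.integer(nfft),
                 sample_rate = sample_rate,
                 bin_width_hz = sample_rate / nfft,
                 col_step_s = hop / sample_rate),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bins x %d columns, %.1f Hz x %.2f ms\n",
              nrow(x$values), ncol(x$values), x$bin_width_hz,
              x$col_step_s * 1000))
  invisible(x)
}

# Exact 3x3 median filter with reflected edge padding, computed as a
# fully vectorised 19-comparator median-of-9 selection network over the
# nine shifted copies of the matrix.
median_filter_3x3 <- function(P) {
  nr <- nrow(P)
  nc <- ncol(P)
  pad <- P[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc), drop = FALSE]
  v <- vector("list", 9L)
  k <- 0L
  for (dc in 0:2) {
    for (dr in 0:2) {
      k <- k + 1L
      v[[k]] <- pad[(1L + dr):(nr + dr), (1L + dc):(nc + dc), drop = FALSE]
    }
  }
  ce <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]])
    v[[j]] <<- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo
  }
  # sort the three columns, then median of (max of mins, median of
  # medians, min of maxes)
  ce(1L, 2L); ce(4L, 5L); ce(7L, 8L)
  ce(2L, 3L); ce(5L, 6L); ce(8L, 9L)
  ce(1L, 2L); ce(4L, 5L); ce(7L, 8L)
  ce(1L, 4L); ce(4L, 7L)              # v7 = max of the three minima
  ce(2L, 5L); ce(5L, 8L); ce(2L, 5L)  # v5 = median of the three medians
  ce(6L, 9L); ce(3L, 6L)              # v3 = min of the three maxima
  ce(3L, 5L); ce(5L, 7L); ce(3L, 5L)  # v5 = median of (v3, v5, v7)
  v[[5L]]
}

#' Enhance a spectrogram (median filter + global scalar offset)
#'
#' Applies an exact 3x3 median filter (reflected edge padding) to remove
#' isolated noise pixels, then adds the global scalar
#' `3 sd(P) - mean(P)` where the statistics are taken over the
#' pre-median matrix: `P' = median(P) + 3 sd(P) - mean(P)`.  The offset
#' is a single number, so pixel ordering is preserved; it interacts only
#' with the absolute-intensity region filter downstream.
#'
#' @param spec a [spectrogram()].
#' @return The enhanced `spectrogram` (with `$enhanced = TRUE`).
#' @export
enhance <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  P <- spec$values
  if (nrow(P) < 3L || ncol(P) < 3L) stop("matrix must be at least 3x3")
  offset <- 3 * stats::sd(P) - mean(P)
  spec$values <- median_filter_3x3(P) + offset
  spec$enhanced <- TRUE
  spec
}

# FFT caches for the disk kernel and the edge-clipped neighborhood
# counts, keyed on image dimensions and radius.
.disk_cache <- new.env(parent = emptyenv())

disk_mask <- function(radius) {
  d <- -radius:radius
  outer(d, d, function(a, b) a^2 + b^2 <= radius^2)
}

# Mean of P over the discrete disk of the given radius centred at each
# pixel, with edge disks clipped to the available pixels.
disk_neighborhood_mean <- function(P, radius) {
  nr <- nrow(P)
  nc <- ncol(P)
  k <- 2L * radius + 1L
  NR <- stats::nextn(nr + k - 1L, c(2L, 3L, 5L))
  NC <- stats::nextn(nc + k - 1L, c(2L, 3L, 5L))
  key <- paste(nr, nc, radius, NR, NC, sep = "_")
  cache <- .disk_cache[[key]]
  if (is.null(cache)) {
    if (length(ls(.disk_cache)) >= 6L) {
      rm(list = ls(.disk_cache), envir = .disk_cache)
    }
    Kp <- matrix(0, NR, NC)
    Kp[seq_len(k), seq_len(k)] <- disk_mask(radius)
    KF <- stats::fft(Kp)
    ones <- matrix(0, NR, NC)
    ones[seq_len(nr), seq_len(nc)] <- 1
    counts <- Re(stats::fft(stats::fft(ones) * KF, inverse = TRUE)) / (NR * NC)
    counts <- counts[radius + seq_len(nr), radius + seq_len(nc), drop = FALSE]
    cache <- list(KF = KF, counts = round(counts))
    .disk_cache[[key]] <- cache
  }
  A <- matrix(0, NR, NC)
  A[seq_len(nr), seq_len(nc)] <- P
  s <- Re(stats::fft(stats::fft(A) * cache$KF, inverse = TRUE)) / (NR * NC)
  s <- s[radius + seq_len(nr), radius + seq_len(nc), drop = FALSE]
  s / cache$counts
}

#' Adaptive circular-neighborhood threshold
#'
#' For each pixel the threshold is the mean intensity over the discrete
#' disk of the given radius (Euclidean centre distance, clipped at the
#' image edges); pixels strictly exceeding their threshold are retained.
#'
#' By default "intensity" is averaged on the linear power scale
#' (`10^(P'/10)`).  Averaging the dB values themselves would retain about
#' half of a homogeneous noise field -- above the 8-connected percolation
#' threshold, so noise would form image-spanning components that no
#' width or intensity rule could remove; the linear-power mean retains
#' `1/e ~ 37%` of noise pixels, keeping noise components small enough for
#' the downstream width filter, which is the regime the morphological
#' cleanup is designed for.  The dB-mean variant remains available.
#'
#' @param spec an enhanced [spectrogram()] (any `spectrogram` works).
#' @param radius neighborhood radius in pixels (default 15).
#' @param scale `"linear"` (default) to average power, `"db"` to average
#'   the dB values.
#' @return A logical matrix, `TRUE` where the pixel is retained.
#' @export
adaptive_threshold <- function(spec, radius = 15L,
                               scale = c("linear", "db")) {
  scale <- match.arg(scale)
  stopifnot(inherits(spec, "spectrogram"), is_number(radius), radius >= 1)
  P <- spec$values
  if (scale == "linear") {
    W <- 10^(P / 10)
    mu <- disk_neighborhood_mean(W, as.integer(radius))
    # strict inequality up to FFT round-off, so a constant image yields
    # an empty mask rather than machine-noise speckle
    W > mu * (1 + 1e-9)
  } else {
    mu <- disk_neighborhood_mean(P, as.integer(radius))
    tol <- 1e-8 * (max(abs(P)) + 1)
    P > mu + tol
  }
}

# 8-connected labeling of a logical mask.  Builds the pixel adjacency
# edge list with vectorised shifts and labels components with igraph.
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  k_all <- which(mask)
  lab <- integer(nr * nc)
  if (length(k_all) == 0L) {
    return(list(labels = matrix(lab, nr, nc), n = 0L))
  }
  id <- integer(nr * nc)
  id[k_all] <- seq_along(k_all)
  r <- ((k_all - 1L) %% nr) + 1L
  co <- ((k_all - 1L) %/% nr) + 1L
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    ok <- r + s[1] >= 1L & r + s[1] <= nr & co + s[2] <= nc
    k2 <- k_all[ok] + s[1] + s[2] * nr
    hit <- mask[k2]
    edges[[length(edges) + 1L]] <- cbind(id[k_all[ok][hit]], id[k2[hit]])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_graph(as.vector(t(e)), n = length(k_all),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[k_all] <- memb
  list(labels = matrix(lab, nr, nc), n = max(memb))
}

#' Extract candidate whistle regions from a binary spectrogram
#'
#' 8-connected component labeling followed by the two morphological
#' filters: components spanning fewer than `min_width` time columns are
#' discarded as click interference, and components whose maximum
#' enhanced value is below `min_peak` are discarded as noise.
#'
#' @param mask logical matrix from [adaptive_threshold()].
#' @param spec the enhanced [spectrogram()] the mask was derived from.
#' @param min_width minimum horizontal extent in columns (default 11).
#' @param min_peak minimum of the component's maximum enhanced value
#'   (default 10, on the enhanced dB scale).
#' @return A list of regions, each a list with `pixels` (linear indices),
#'   `rows`, `cols`, `width`, `max_value`; dropped components are counted
#'   in attributes `n_dropped_width` and `n_dropped_intensity`.
#' @export
extract_regions <- function(mask, spec, min_width = 11L, min_peak = 10) {
  stopifnot(is.logical(mask), inherits(spec, "spectrogram"),
            all(dim(mask) == dim(spec$values)))
  lab <- label_components(mask)
  if (lab$n == 0L) {
    return(structure(list(), n_dropped_width = 0L, n_dropped_intensity = 0L))
  }
  k_all <- which(mask)
  memb <- lab$labels[k_all]
  nr <- nrow(mask)
  co <- ((k_all - 1L) %/% nr) + 1L
  val <- spec$values[k_all]
  # per-component column range and intensity maximum, vectorised via
  # ordering + group boundaries
  o <- order(memb, co)
  ends <- cumsum(tabulate(memb, lab$n))
  starts <- c(1L, ends[-lab$n] + 1L)
  cmin <- co[o][starts]
  cmax <- co[o][ends]
  ov <- order(memb, val)
  vmax <- val[ov][ends]
  width <- cmax - cmin + 1L
  keep <- which(width >= min_width & vmax >= min_peak)
  ndw <- sum(width < min_width)
  ndi <- sum(width >= min_width & vmax < min_peak)
  keep <- keep[order(cmin[keep])]
  by_comp <- split(k_all, memb)
  out <- lapply(keep, function(ci) {
    k <- by_comp[[ci]]
    list(pixels = k, rows = ((k - 1L) %% nr) + 1L,
         cols = ((k - 1L) %/% nr) + 1L,
         width = width[ci], max_value = vmax[ci])
  })
  structure(out, n_dropped_width = ndw, n_dropped_intensity = ndi)
}

#' Extract the frequency ridge of a whistle region
#'
#' For each occupied time column the ridge frequency is the
#' linear-magnitude-weighted centroid of the region's pixels in that
#' column; single-column gaps are linearly interpolated and flagged, and
#' the contour is smoothed with a 5-point running median.
#'
#' @param region one region from [extract_regions()].
#' @param spec the enhanced [spectrogram()].
#' @return An object of class `whistle_contour`: list with `cols`,
#'   `times_s`, `freq_khz` (smoothed ridge), `freq_raw_khz`,
#'   `interpolated` (logical), `col_step_s`, `onset_s`.
#' @export
ridge_contour <- function(region, spec) {
  stopifnot(inherits(spec, "spectrogram"))
  w <- from_dB(spec$values[region$pixels])
  f <- spec$freq_khz[region$rows]
  num <- rowsum(w * f, region$cols)
  den <- rowsum(w, region$cols)
  cols_present <- as.integer(rownames(num))
  ridge <- as.numeric(num / den)
  cols_full <- seq(min(cols_present), max(cols_present))
  interp <- !(cols_full %in% cols_present)
  freq <- if (any(interp)) {
    stats::approx(cols_present, ridge, xout = cols_full)$y
  } else {
    ridge
  }
  sm <- if (length(freq) >= 5L) {
    as.numeric(stats::runmed(freq, 5L, endrule = "median"))
  } else {
    freq
  }
  structure(list(cols = cols_full, times_s = spec$times_s[cols_full],
                 freq_khz = sm, freq_raw_khz = freq,
                 interpolated = interp, col_step_s = spec$col_step_s,
                 onset_s = spec$times_s[cols_full[1L]]),
            class = "whistle_contour")
}

#' Measure a whistle contour
#'
#' @param contour a [ridge_contour()].
#' @return An object of class `whistle_metrics`: `duration_ms`, `bf_khz`
#'   (beginning), `ef_khz` (ending), `minf_khz`, `maxf_khz`, `range_khz`.
#' @export
measure_whistle <- function(contour) {
  stopifnot(inherits(contour, "whistle_contour"))
  f <- contour$freq_khz
  if (length(f) < 2L) stop("contour must have at least 2 points")
  structure(list(
    duration_ms = (length(f) - 1L) * contour$col_step_s * 1000,
    bf_khz = f[1L], ef_khz = f[length(f)],
    minf_khz = min(f), maxf_khz = max(f),
    range_khz = max(f) - min(f)
  ), class = "whistle_metrics")
}

#' Classify a whistle contour into one of six shape types
#'
#' Deterministic rules on the median-smoothed ridge with tolerance
#' `delta = max(0.25 kHz, 5% of the mean frequency)`: `constant` if the
#' frequency range is below `2 delta`; otherwise interior turning points
#' are counted with delta-hysteresis -- 0 turns gives `upsweep` or
#' `downsweep` by the sign of end minus start, 1 turn gives `convex`
#' (interior maximum) or `concave` (interior minimum), and 2 or more
#' turns give `sinusoidal`.
#'
#' @param contour a [ridge_contour()].
#' @param tol_khz absolute tolerance floor, kHz.
#' @param tol_frac relative tolerance as a fraction of mean frequency.
#' @return One of `"constant"`, `"upsweep"`, `"downsweep"`, `"concave"`,
#'   `"convex"`, `"sinusoidal"`.
#' @export
classify_shape <- function(contour, tol_khz = 0.25, tol_frac = 0.05) {
  stopifnot(inherits(contour, "whistle_contour"))
  f <- contour$freq_khz
  delta <- max(tol_khz, tol_frac * mean(f))
  if (max(f) - min(f) < 2 * delta) return("constant")
  dir <- 0L
  ref <- f[1L]
  turns <- 0L
  first_dir <- 0L
  for (v in f[-1L]) {
    if (dir == 0L) {
      if (v - ref >= delta) {
        dir <- 1L
        first_dir <- 1L
        ref <- v
      } else if (ref - v >= delta) {
        dir <- -1L
        first_dir <- -1L
        ref <- v
      }
    } else if (dir == 1L) {
      if (v > ref) {
        ref <- v
      } else if (ref - v >= delta) {
        turns <- turns + 1L
        dir <- -1L
        ref <- v
      }
    } else {
      if (v < ref) {
        ref <- v
      } else if (v - ref >= delta) {
        turns <- turns + 1L
        dir <- 1L
        ref <- v
      }
    }
  }
  if (turns == 0L) {
    if (f[length(f)] > f[1L]) "upsweep" else "downsweep"
  } else if (turns == 1L) {
    if (first_dir == 1L) "convex" else "concave"
  } else {
    "sinusoidal"
  }
}

#' Detect and measure whistles in a segment
#'
#' Runs the full tonal-detection chain -- spectrogram, enhancement,
#' adaptive thresholding, connected-component filtering, ridge
#' extraction, metrics and shape classification -- on a whole segment,
#' or frame by frame (with de-duplication of detections repeated in the
#' overlap, onset within 5 ms) when a [frame_spec()] is supplied.
#'
#' @param segment an [audio_segment()].
#' @param hop STFT hop, samples.
#' @param radius adaptive-threshold neighborhood radius, pixels.
#' @param min_width minimum component width, columns.
#' @param min_peak minimum component maximum enhanced value.
#' @param max_freq_khz upper edge of the analysis band (default 32 kHz);
#'   whistle fundamentals for this species sit at 2-16 kHz, so bins above
#'   the band carry no tonal information and are excluded before
#'   enhancement.  Set to `NULL` to analyse the full band.
#' @param frames optional [frame_spec()] for framed processing.
#' @return A list with `contours` (list of annotated `whistle_contour`s,
#'   each with `$metrics` and `$shape` filled) and `summary` (data frame
#'   with onset_s, duration_ms, bf_khz, ef_khz, minf_khz, maxf_khz,
#'   range_khz, shape).
#' @export
detect_whistles <- function(segment, hop = 512L, radius = 15L,
                            min_width = 11L, min_peak = 10,
                            max_freq_khz = 32, frames = NULL) {
  stopifnot(inherits(segment, "audio_segment"))
  run_one <- function(samples, t0) {
    sp <- spectrogram(samples, segment$sample_rate, hop = hop)
    sp$times_s <- sp$times_s + t0
    if (!is.null(max_freq_khz)) {
      keep <- sp$freq_khz <= max_freq_khz
      sp$values <- sp$values[keep, , drop = FALSE]
      sp$freq_khz <- sp$freq_khz[keep]
    }
    spe <- enhance(sp)
    mask <- adaptive_threshold(spe, radius)
    regions <- extract_regions(mask, spe, min_width, min_peak)
    lapply(regions, function(rg) {
      ct <- ridge_contour(rg, spe)
      ct$metrics <- measure_whistle(ct)
      ct$shape <- classify_shape(ct)
      ct
    })
  }
  contours <- if (is.null(frames)) {
    run_one(segment$samples, segment$start_time)
  } else {
    all <- list()
    for (fr in frame_stream(segment, frames)) {
      if (length(fr$samples) < 1024L) next
      for (ct in run_one(fr$samples, fr$start_time)) {
        dup <- any(vapply(all, function(prev)
          abs(prev$onset_s - ct$onset_s) < 5e-3 &&
            abs(stats::median(prev$freq_khz) -
                  stats::median(ct$freq_khz)) < 1, TRUE))
        if (!dup) all[[length(all) + 1L]] <- ct
      }
    }
    all
  }
  grab <- function(fld) vapply(contours, function(ct) ct$metrics[[fld]], 0)
  summary <- data.frame(
    onset_s = vapply(contours, function(ct) ct$onset_s, 0),
    duration_ms = grab("duration_ms"), bf_khz = grab("bf_khz"),
    ef_khz = grab("ef_khz"), minf_khz = grab("minf_khz"),
    maxf_khz = grab("maxf_khz"), range_khz = grab("range_khz"),
    shape = vapply(contours, function(ct) ct$shape, ""),
    stringsAsFactors = FALSE)
  list(contours = contours, summary = summary)
}
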