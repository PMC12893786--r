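# Transient (click) detection: Teager-Kaiser energy, matched-gain
# Gaussian/rectangular smoothing, the Filter Difference Ratio, candidate
# extraction and the pluggable click/non-click classifier.

#' Click detector configuration
#'
#' @param fwhm_ms full width at half maximum of the Gaussian smoothing
#'   kernel, milliseconds (default 0.10).
#' @param fdr_threshold detection threshold on the Filter Difference
#'   Ratio, in (0, 1) (default 0.7).
#' @param refractory_ms detections closer than this are merged into one
#'   event (default 1.0 ms).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(fwhm_ms = 0.10, fdr_threshold = 0.7,
                            refractory_ms = 1.0) {
  stopifnot(is_number(fwhm_ms), fwhm_ms > 0,
            is_number(fdr_threshold), fdr_threshold > 0, fdr_threshold < 1,
            is_number(refractory_ms), refractory_ms >= 0)
  structure(list(fwhm_ms = fwhm_ms, fdr_threshold = fdr_threshold,
                 refractory_ms = refractory_ms), class = "detector_config")
}

#' Teager-Kaiser energy operator
#'
#' `Psi[n] = x[n]^2 - x[n-1] x[n+1]` for interior samples; the two
#' endpoints are set to 0 so the series stays aligned with the input.
#'
#' @param samples numeric vector of length >= 3.
#' @return Numeric vector of the same length.
#' @export
tkeo <- function(samples) {
  n <- length(samples)
  if (n < 3L) stop("tkeo needs at least 3 samples")
  psi <- numeric(n)
  psi[2:(n - 1L)] <- samples[2:(n - 1L)]^2 -
    samples[1:(n - 2L)] * samples[3:n]
  psi
}

#' Matched-gain Gaussian and rectangular smoothing kernels
#'
#' The Gaussian kernel has taps
#' `Ts/(sigma_G sqrt(2 pi)) exp(-(n Ts)^2 / (2 sigma_G^2))` for
#' `n = -N..N` with `sigma_G = FWHM / (2 sqrt(2 ln 2))`, and `2N + 1`
#' spanning four FWHMs.  The rectangular kernel has the same length and
#' each tap equal to the mean Gaussian tap, so both kernels have exactly
#' the same total gain.
#'
#' @param config a [detector_config()].
#' @param sample_rate sampling rate, Hz.
#' @return A list with `gaussian`, `rect` (numeric kernels) and `N`.
#' @export
build_kernels <- function(config, sample_rate) {
  stopifnot(inherits(config, "detector_config"), is_number(sample_rate))
  fwhm <- config$fwhm_ms / 1000
  sigma_g <- fwhm / (2 * sqrt(2 * log(2)))
  ts <- 1 / sample_rate
  N <- max(ceiling((4 * fwhm / ts - 1) / 2), 1L)
  n <- -N:N
  g <- ts / (sigma_g * sqrt(2 * pi)) * exp(-(n * ts)^2 / (2 * sigma_g^2))
  r <- rep(sum(g) / (2 * N + 1), 2 * N + 1)
  list(gaussian = g, rect = r, N = as.integer(N))
}

#' Filter Difference Ratio series
#'
#' Smooths a TKEO energy series with the matched-gain Gaussian and
#' rectangular kernels (same-length zero-padded convolution, so the
#' output stays index-aligned with the samples) and forms
#' `FDR[n] = (h1[n] - h2[n]) / h1[n]` where `h1 > 0`, else 0.  The ratio
#' is near 0 on stationary noise and approaches `1 - mean(g)/max(g)` at
#' an isolated impulse.
#'
#' @param energy TKEO energy series.
#' @param kernels kernels from [build_kernels()].
#' @return Numeric FDR series, same length as `energy`.
#' @export
fdr_series <- function(energy, kernels) {
  stopifnot(is.numeric(energy), all(is.finite(energy)))
  h <- conv_same_dual(energy, kernels$gaussian, kernels$rect)
  h1 <- h$a
  h2 <- h$b
  out <- numeric(length(energy))
  pos <- h1 > 0
  out[pos] <- (h1[pos] - h2[pos]) / h1[pos]
  out
}

# Merge index runs whose gaps are below `gap`; x is a sorted integer
# vector of above-threshold indices.  Returns a matrix of run start/end.
merge_runs <- function(x, gap) {
  if (length(x) == 0L) return(matrix(integer(0), ncol = 2L))
  brk <- which(diff(x) > gap)
  starts <- x[c(1L, brk + 1L)]
  ends <- x[c(brk, length(x))]
  cbind(starts, ends)
}

#' Detect click candidates in a (high-passed) segment
#'
#' Thresholds the FDR series, merges contiguous runs and runs closer than
#' the refractory interval, places one candidate at the TKEO maximum of
#' each run, and extracts a peak-referenced window around it.
#'
#' @param segment a high-passed [audio_segment()].
#' @param config a [detector_config()].
#' @return A list of candidates, each a list with `peak_index`,
#'   `peak_time_s`, `fdr_at_peak`, `window`, `window_start`, `truncated`,
#'   `label` (initially `"unlabeled"`) and `score` (NA until classified).
#' @export
detect_candidates <- function(segment, config = detector_config()) {
  stopifnot(inherits(segment, "audio_segment"))
  x <- segment$samples
  if (length(x) < 3L) return(list())
  kernels <- build_kernels(config, segment$sample_rate)
  psi <- tkeo(x)
  fdr <- fdr_series(psi, kernels)
  above <- which(fdr > config$fdr_threshold)
  gap <- max(round(config$refractory_ms / 1000 * segment$sample_rate), 1L)
  runs <- merge_runs(above, gap)
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    rng <- runs[i, 1L]:runs[i, 2L]
    peak <- rng[which.max(psi[rng])]
    win <- extract_click_window(x, peak, segment$sample_rate)
    out[[i]] <- list(peak_index = peak,
                     peak_time_s = segment$start_time +
                       (peak - 1L) / segment$sample_rate,
                     fdr_at_peak = fdr[peak],
                     window = win$window,
                     window_start = win$start_index,
                     truncated = win$truncated,
                     label = "unlabeled", score = NA_real_)
  }
  out
}

#' Extract a peak-referenced click window
#'
#' Grows a window symmetrically from the envelope peak until the Hilbert
#' envelope stays below -20 dB of the peak for 10 consecutive samples on
#' each side, capped at +/-150 us.  A window cut short by the segment
#' edge is flagged, not dropped.
#'
#' @param samples pressure series (vector) containing the click.
#' @param peak_index sample index of the detected peak.
#' @param sample_rate sampling rate, Hz.
#' @param drop_db envelope decay threshold below the peak, dB.
#' @param hold_samples consecutive below-threshold samples required.
#' @param max_half_us maximum half-width, microseconds.
#' @return A list with `window`, `start_index` and `truncated`.
#' @export
extract_click_window <- function(samples, peak_index, sample_rate,
                                 drop_db = 20, hold_samples = 10L,
                                 max_half_us = 150) {
  L <- length(samples)
  stopifnot(peak_index >= 1L, peak_index <= L)
  max_half <- max(round(max_half_us * 1e-6 * sample_rate), hold_samples)
  margin <- 16L
  lo <- max(1L, peak_index - max_half - margin)
  hi <- min(L, peak_index + max_half + margin)
  env <- envelope(samples[lo:hi])
  p <- peak_index - lo + 1L
  thr <- env[p] * from_dB(-drop_db)
  grow <- function(dir) {
    run <- 0L
    k <- p
    limit <- if (dir > 0) min(length(env), p + max_half) else max(1L, p - max_half)
    while (k != limit) {
      k <- k + dir
      run <- if (env[k] < thr) run + 1L else 0L
      if (run >= hold_samples) return(list(edge = k, truncated = FALSE))
    }
    at_seg_edge <- (dir > 0 && hi == L && limit == length(env)) ||
      (dir < 0 && lo == 1L && limit == 1L)
    list(edge = limit, truncated = at_seg_edge && run < hold_samples)
  }
  left <- grow(-1L)
  right <- grow(1L)
  idx <- (lo + left$edge - 1L):(lo + right$edge - 1L)
  list(window = samples[idx], start_index = idx[1L],
       truncated = left$truncated || right$truncated)
}

#' Level-independent features of a click window
#'
#' Fixed-order feature vector used by the click/non-click classifier:
#' 95%-energy duration (us), peak frequency (kHz), -3 dB bandwidth (kHz),
#' spectral centroid (kHz), crest factor, and the fraction of spectral
#' energy above 100 kHz.  All features are invariant to amplitude
#' scaling, so a classifier trained on them never keys on level.
#'
#' @param window click window, pressure.
#' @param sample_rate sampling rate, Hz.
#' @return Named numeric vector of length 6.
#' @export
click_features <- function(window, sample_rate) {
  if (all(window == 0)) stop("cannot compute features of an all-zero window")
  m <- measure_click(window, sample_rate)
  sp <- click_spectrum(window, sample_rate)
  pow <- sp$mag^2
  centroid <- sum(sp$freq * pow) / sum(pow) / 1000
  crest <- max(abs(window)) / rms(window)
  hf <- sum(pow[sp$freq > 100e3]) / sum(pow)
  c(duration_us = m$duration_us, fp_khz = m$fp_khz, bw3_khz = m$bw3_khz,
    centroid_khz = centroid, crest = crest, hf_ratio = hf)
}

# Label candidates by proximity to annotated events: "click" within
# tol_s of a true click onset-offset midpoint, otherwise "other".
label_candidates_from_truth <- function(candidates, annotation,
                                        tol_s = 5e-4) {
  clicks <- annotation[annotation$event_class == "click", , drop = FALSE]
  mids <- (clicks$onset_s + clicks$offset_s) / 2
  vapply(candidates, function(cd) {
    if (length(mids) > 0L && any(abs(cd$peak_time_s - mids) <= tol_s)) {
      "click"
    } else {
      "other"
    }
  }, "")
}

#' Train the click/non-click classifier on synthetic scenes
#'
#' Renders the supplied scene configurations, runs detection, labels each
#' candidate from the scene's ground truth, and fits a single-hidden-layer
#' feed-forward network (logistic output) on the level-independent
#' features.  The classifier is pluggable: [classify_candidates()] accepts
#' any substitute scorer function in its place.
#'
#' @param training_configs list of [scene_config()] objects containing
#'   both clicks and non-click transients (e.g. snaps).
#' @param config a [detector_config()].
#' @param hidden_units hidden layer size (default 32).
#' @param seed RNG seed for the network initialisation.
#' @return An object of class `click_classifier`.
#' @export
train_click_classifier <- function(training_configs,
                                   config = detector_config(),
                                   hidden_units = 32L, seed = 42L) {
  feats <- list()
  labels <- character(0)
  for (cfg in training_configs) {
    scene <- render_scene(cfg)
    seg <- highpass(scene$segment)
    cands <- detect_candidates(seg, config)
    if (length(cands) == 0L) next
    lab <- label_candidates_from_truth(cands, scene$annotation)
    for (i in seq_along(cands)) {
      f <- tryCatch(click_features(cands[[i]]$window, seg$sample_rate),
                    error = function(e) NULL)
      if (!is.null(f) && all(is.finite(f))) {
        feats[[length(feats) + 1L]] <- f
        labels <- c(labels, lab[i])
      }
    }
  }
  if (length(unique(labels)) < 2L) {
    stop("training scenes must yield candidates of both classes")
  }
  X <- do.call(rbind, feats)
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- scale(X, mu, sdev)
  y <- as.integer(labels == "click")
  net <- with_seed(seed, nnet::nnet(Xs, y, size = hidden_units,
                                    decay = 5e-3, maxit = 300,
                                    entropy = TRUE, trace = FALSE))
  structure(list(net = net, center = mu, scale = sdev,
                 threshold = 0.5, n_train = length(y)),
            class = "click_classifier")
}

#' Score and label detected candidates
#'
#' @param candidates candidate list from [detect_candidates()].
#' @param classifier a `click_classifier` from
#'   [train_click_classifier()], or any function mapping a feature
#'   vector (see [click_features()]) to a score in `[0, 1]`.
#' @param sample_rate sampling rate of the candidates' windows, Hz.
#' @return The candidate list with `score` filled in and `label` set to
#'   `"click"` where score >= 0.5, else `"other"`.
#' @export
classify_candidates <- function(candidates, classifier, sample_rate) {
  score_one <- function(f) {
    if (is.function(classifier)) return(classifier(f))
    fs <- scale(matrix(f, nrow = 1L), classifier$center, classifier$scale)
    as.numeric(stats::predict(classifier$net, fs))
  }
  thr <- if (is.function(classifier)) 0.5 else classifier$threshold
  lapply(candidates, function(cd) {
    f <- tryCatch(click_features(cd$window, sample_rate),
                  error = function(e) NULL)
    cd$score <- if (is.null(f) || any(!is.finite(f))) 0 else score_one(f)
    cd$label <- if (cd$score >= thr) "click" else "other"
    cd
  })
}

#' Optional reverberation screen for extracted clicks
#'
#' Flags windows whose Hilbert envelope shows a secondary lobe above
#' -10 dB of the main peak within 150 us after it -- a simple,
#' configurable screen for surface/bottom reflections following the
#' direct path.
#'
#' @param window click window.
#' @param sample_rate sampling rate, Hz.
#' @param lobe_db secondary-lobe threshold below the peak, dB.
#' @param horizon_us search horizon after the main peak, us.
#' @return `TRUE` if the window should be rejected as reverberant.
#' @export
screen_reverberant <- function(window, sample_rate, lobe_db = 10,
                               horizon_us = 150) {
  env <- envelope(window)
  p <- which.max(env)
  thr <- env[p] * from_dB(-lobe_db)
  hi <- min(length(env), p + round(horizon_us * 1e-6 * sample_rate))
  if (hi <= p + 2L) return(FALSE)
  seg <- env[(p + 1L):hi]
  below <- seg < thr
  if (!any(below)) return(FALSE)
  first_drop <- which(below)[1L]
  any(seg[first_drop:length(seg)] >= thr)
}

#' Score detections against a scene annotation
#'
#' Matches click-labeled candidates to annotated click events within a
#' time tolerance and reports precision and recall.
#'
#' @param candidates classified candidate list.
#' @param annotation annotation data frame from [render_scene()].
#' @param tol_s matching tolerance around the true peak time, seconds.
#' @return A list with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
score_click_detections <- function(candidates, annotation, tol_s = 5e-4) {
  clicks <- annotation[annotation$event_class == "click", , drop = FALSE]
  truth <- (clicks$onset_s + clicks$offset_s) / 2
  det <- vapply(candidates, function(cd) cd$peak_time_s, 0)[
    vapply(candidates, function(cd) cd$label == "click", TRUE)]
  matched <- logical(length(truth))
  tp <- 0L
  fp <- 0L
  for (t in det) {
    d <- abs(truth - t)
    d[matched] <- Inf
    if (length(d) > 0L && min(d) <= tol_s) {
      matched[which.min(d)] <- TRUE
      tp <- tp + 1L
    } else {
      fp <- fp + 1L
    }
  }
  fn <- sum(!matched)
  list(precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
       recall = if (length(truth) > 0L) tp / length(truth) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
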