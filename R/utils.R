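# Internal numeric helpers shared across modules.

#' Convert a linear pressure ratio to decibels
#'
#' @param x positive linear value (e.g. pressure in micropascal).
#' @return `20 * log10(x)`.
#' @keywords internal
dB <- function(x) 20 * log10(x)

#' Convert decibels to a linear value
#' @param x value in dB.
#' @return `10^(x / 20)`.
#' @keywords internal
from_dB <- function(x) 10^(x / 20)

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Linear full convolution via FFT; kernel assumed much shorter than x.
fft_conv_full <- function(x, k) {
  n_out <- length(x) + length(k) - 1L
  n <- stats::nextn(n_out, 2L)
  xf <- stats::fft(c(x, numeric(n - length(x))))
  kf <- stats::fft(c(k, numeric(n - length(k))))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n_out)] / n
}

# Same-length zero-padded convolution with an odd, centred kernel.
# Long inputs are processed by overlap-add so memory stays bounded.
# A real input may be convolved with two kernels in one FFT pass by
# packing them as kernel1 + 1i * kernel2 (Re/Im of the result).
conv_same <- function(x, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  full <- conv_full_blocked(x, kernel)
  Re(full)[(half + 1L):(half + length(x))]
}

conv_same_dual <- function(x, kernel1, kernel2) {
  half <- (length(kernel1) - 1L) %/% 2L
  full <- conv_full_blocked(x, kernel1 + 1i * kernel2)
  idx <- (half + 1L):(half + length(x))
  list(a = Re(full)[idx], b = Im(full)[idx])
}

conv_full_blocked <- function(x, kernel) {
  L <- length(x)
  nk <- length(kernel)
  if (L <= 2^20) {
    n <- stats::nextn(L + nk - 1L, 2L)
    kf <- stats::fft(c(kernel, numeric(n - nk)))
    return(stats::fft(stats::fft(c(x, numeric(n - L))) * kf,
                      inverse = TRUE)[seq_len(L + nk - 1L)] / n)
  }
  n <- 2^20
  step <- n - nk + 1L
  kf <- stats::fft(c(kernel, numeric(n - nk)))
  full <- complex(L + nk - 1L)
  for (s in seq(1L, L, by = step)) {
    e <- min(L, s + step - 1L)
    xb <- x[s:e]
    nb <- length(xb)
    seg <- stats::fft(stats::fft(c(xb, numeric(n - nb))) * kf,
                      inverse = TRUE)[seq_len(nb + nk - 1L)] / n
    idx <- s:(e + nk - 1L)
    full[idx] <- full[idx] + seg
  }
  full
}

# Magnitude of the analytic signal (FFT-based Hilbert envelope).
envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Truncated-normal draws (lower truncation only) by rejection; the
# truncation points used in this package sit far into the tail, so the
# acceptance rate is essentially 1.
r_truncnorm <- function(n, mean, sd, lower = -Inf) {
  out <- numeric(0L)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

# Lognormal parameterised by its arithmetic mean and SD.
lognormal_pars <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

r_lognormal_ms <- function(n, mean, sd) {
  p <- lognormal_pars(mean, sd)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

# RMS of a pressure series.
rms <- function(x) sqrt(mean(x^2))

# Band-limited (FFT) interpolation by an integer factor; input is
# zero-padded by the caller if guard samples are needed.
fft_interp <- function(x, factor = 4L) {
  if (length(x) %% 2L == 1L) x <- c(x, 0)
  N <- length(x)
  M <- factor * N
  h <- N %/% 2L
  X <- stats::fft(x)
  Xn <- complex(M)
  Xn[seq_len(h)] <- X[seq_len(h)]
  Xn[h + 1L] <- X[h + 1L] / 2
  Xn[M - h + 1L] <- Conj(X[h + 1L]) / 2
  if (h > 1L) Xn[(M - h + 2L):M] <- X[(h + 2L):N]
  Re(stats::fft(Xn, inverse = TRUE)) / N
}

# Hilbert envelope of a transient snippet, computed on a zero-padded,
# band-limited 4x oversampled copy: padding suppresses the circular
# wrap-around of the analytic transform on short windows, oversampling
# removes quantile discretisation when the envelope spans few samples.
# Returns the envelope and its effective sample rate.
envelope_fine <- function(x, sample_rate, factor = 4L) {
  guard <- max(64L, length(x) %/% 2L)
  xi <- fft_interp(c(x, numeric(guard)), factor)
  list(env = envelope(xi)[seq_len(factor * length(x))],
       sample_rate = sample_rate * factor)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Direct-form IIR filtering with zero initial conditions via the C loops
# in stats::filter (MA part by convolution, AR part recursively).
iir_filter <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  nb <- length(b)
  z <- as.numeric(stats::filter(x, b, method = "convolution", sides = 1L))
  for (i in seq_len(min(nb - 1L, length(x)))) {
    z[i] <- sum(b[seq_len(i)] * x[i:1L])
  }
  if (length(a) > 1L) {
    z <- as.numeric(stats::filter(z, -a[-1L], method = "recursive"))
  }
  z / a[1L]
}

# Forward-backward (zero-phase) application of an IIR filter.  Edge
# transients decay within a few filter lengths; inputs here are long
# noise-dominated segments where that is immaterial.
zero_phase_filter <- function(filt, x) {
  rev(iir_filter(filt, rev(iir_filter(filt, x))))
}
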