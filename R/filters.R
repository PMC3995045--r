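#' Band-pass filter specification
#'
#' Zero-phase FIR band-pass design used throughout the event detectors:
#' windowed-sinc (Hamming) of even order, applied forward-backward. The
#' design grid step `design_resolution_hz` quantizes the band edges (10 Hz
#' for the ripple band, 0.5 Hz for the spindle band).
#'
#' @param band_lo_hz,band_hi_hz Pass-band edges in Hz (0 < lo < hi).
#' @param order Filter order (taps - 1), even, default 512.
#' @param design_resolution_hz Frequency grid step used in design; band
#'   edges are rounded to this grid.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(band_lo_hz, band_hi_hz, order = 512,
                        design_resolution_hz = 10) {
  if (!(band_lo_hz > 0) || !(band_hi_hz > band_lo_hz))
    stop("invalid band: need 0 < band_lo < band_hi")
  order <- as.integer(order)
  if (order < 2L || order %% 2L != 0L) stop("order must be even and >= 2")
  lo <- round(band_lo_hz / design_resolution_hz) * design_resolution_hz
  hi <- round(band_hi_hz / design_resolution_hz) * design_resolution_hz
  if (lo <= 0) lo <- band_lo_hz
  structure(list(band_lo_hz = lo, band_hi_hz = hi, order = order,
                 design_resolution_hz = design_resolution_hz),
            class = "filter_spec")
}

# FIR taps for a spec at a given sampling rate (Hamming windowed-sinc).
fir_taps <- function(spec, fs) {
  if (spec$band_hi_hz >= fs / 2) stop("band exceeds Nyquist")
  signal::fir1(spec$order, c(spec$band_lo_hz, spec$band_hi_hz) / (fs / 2),
               type = "pass")
}

# Linear convolution via FFT, causal "same" output (first length(x) samples).
# Frees intermediates eagerly: on multi-minute wide-band recordings the
# complex temporaries are ~200 MB each.
fft_conv_same <- function(b, x) {
  nb <- length(b); nx <- length(x)
  big <- nx > 5e6
  nfft <- stats::nextn(nx + nb - 1L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - nx)))
  X <- X * stats::fft(c(b, numeric(nfft - nb)))
  if (big) gc(FALSE)
  y <- stats::fft(X, inverse = TRUE)
  rm(X)
  y <- Re(y)[seq_len(nx)] / nfft
  if (big) gc(FALSE)
  y
}

reflect_pad <- function(x, p) {
  n <- length(x)
  if (p >= n) stop("insufficient samples for filter order")
  c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
}

#' Zero-phase band-pass filtering
#'
#' Applies the FIR filter forward then backward so the net phase shift is
#' zero and the effective magnitude response is the squared single-pass
#' response. The signal is reflect-padded by `3 * (order + 1)` samples on
#' each side before filtering to suppress onset transients.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 2000; t <- seq(0, 1, by = 1 / fs)
#' y <- bandpass_zerophase(sin(2 * pi * 150 * t), fs, filter_spec(100, 600))
#' @export
bandpass_zerophase <- function(x, fs, spec) {
  if (!inherits(spec, "filter_spec")) stop("spec must be a filter_spec")
  ntaps <- spec$order + 1L
  if (length(x) <= 3L * ntaps) stop("insufficient samples for filter order")
  b <- fir_taps(spec, fs)
  pad <- 3L * ntaps
  xp <- reflect_pad(x, pad)
  y <- fft_conv_same(b, xp)
  rm(xp)
  y <- rev(fft_conv_same(b, rev(y)))
  y[(pad + 1):(pad + length(x))]
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; reproduces any polynomial of
#' degree `<= polyorder` exactly on interior samples.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_ms Smoothing window length in milliseconds (rounded up to an
#'   odd number of samples). Default 5 ms.
#' @param polyorder Polynomial degree, default 3.
#' @return Smoothed signal, same length as `x`.
#' @export
savgol_smooth <- function(x, fs, window_ms = 5, polyorder = 3) {
  n <- max(3L, round(window_ms * fs / 1000))
  if (n %% 2L == 0L) n <- n + 1L
  if (n <= polyorder) stop("invalid smoother configuration: window <= polyorder")
  if (length(x) <= n) stop("invalid smoother configuration: signal shorter than window")
  signal::sgolayfilt(x, p = polyorder, n = n)
}

#' Hilbert (analytic-signal) envelope
#'
#' Magnitude of the analytic signal, computed by one-sided spectral
#' doubling on a 5-smooth zero-padded FFT length. Edge transients decay as
#' 1/t from each end; time-reversing pads are deliberately avoided because
#' they flip the sign of instantaneous frequency and corrupt the analytic
#' signal of narrow-band inputs.
#'
#' @param x Numeric signal (finite, non-empty).
#' @return Non-negative envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  Mod(analytic_signal(x))
}

analytic_signal <- function(x) {
  if (length(x) == 0) stop("empty signal")
  if (!all(is.finite(x))) stop("invalid samples: non-finite values")
  n <- length(x)
  pad <- 0L
  nfft <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  h <- numeric(nfft)
  h[1] <- 1
  if (nfft %% 2L == 0L) {
    h[nfft / 2 + 1] <- 1
    h[2:(nfft / 2)] <- 2
  } else {
    h[2:((nfft + 1) / 2)] <- 2
  }
  X <- X * h
  if (nfft > 5e6) gc(FALSE)
  a <- stats::fft(X, inverse = TRUE) / nfft
  rm(X)
  a[(pad + 1):(pad + n)]
}

# Exact Fourier resampling to a lower rate; fs/fs_new must be an integer.
fourier_decimate <- function(x, fs, fs_new) {
  r <- fs / fs_new
  if (abs(r - round(r)) > 1e-9) stop("fs/fs_new must be an integer")
  r <- round(r)
  if (r == 1) return(x)
  n <- length(x)
  m <- floor(n / r)
  x <- x[seq_len(m * r)]
  X <- stats::fft(x)
  keep <- m %/% 2
  Y <- complex(m)
  Y[1] <- X[1]
  if (keep >= 1) {
    Y[2:(keep + 1)] <- X[2:(keep + 1)]
    Y[(m - keep + 1):m] <- X[(m * r - keep + 1):(m * r)]
  }
  Re(stats::fft(Y, inverse = TRUE)) / (m * r)
}
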