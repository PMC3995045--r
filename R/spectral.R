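#' Averaged power spectrum in decibels
#'
#' Splits a signal into non-overlapping segments, computes Hamming-tapered
#' one-sided periodograms and averages them in the linear domain before
#' conversion to decibels (`10*log10`, reference 1 uV^2/Hz). The PSD is
#' normalized so a unit-amplitude tone integrates to 0.5 uV^2.
#'
#' When the requested `resolution_hz` is finer than the native segment
#' resolution, segments are zero-padded; when coarser, native-resolution
#' periodogram bins are averaged onto the requested grid.
#'
#' @param x Numeric signal in microvolts.
#' @param fs Sampling rate in Hz.
#' @param segment_s Segment length in seconds (default 1).
#' @param resolution_hz Frequency grid step of the output (default 1).
#' @return An object of class `power_spectrum` with fields `freqs_hz`,
#'   `power_db`, `resolution_hz`, `n_segments`.
#' @examples
#' fs <- 1000; t <- seq(0, 10 - 1 / fs, by = 1 / fs)
#' sp <- average_spectrum(sin(2 * pi * 6 * t), fs)
#' peak_frequency(sp, c(1, 20))
#' @export
average_spectrum <- function(x, fs, segment_s = 1, resolution_hz = 1) {
  nseg <- round(segment_s * fs)
  if (length(x) < nseg) stop("insufficient data: signal shorter than one segment")
  k <- floor(length(x) / nseg)
  w <- hamming_window(nseg)
  norm <- fs * sum(w^2)
  nfft_req <- round(fs / resolution_hz)
  nfft <- max(nseg, nfft_req)
  acc <- NULL
  for (i in seq_len(k)) {
    seg <- x[((i - 1) * nseg + 1):(i * nseg)] * w
    P <- onesided_psd(seg, nfft, norm)
    acc <- if (is.null(acc)) P else acc + P
  }
  P <- acc / k
  native_res <- fs / nfft
  if (nfft_req < nseg) {
    rg <- regrid_psd(P, native_res, resolution_hz, fs)
    P <- rg$P; freqs <- rg$freqs
  } else {
    freqs <- (seq_along(P) - 1) * native_res
    resolution_hz <- native_res
  }
  new_power_spectrum(freqs, 10 * log10(pmax(P, .Machine$double.xmin)),
                     resolution_hz, k)
}

new_power_spectrum <- function(freqs_hz, power_db, resolution_hz, n_segments,
                               normalized = FALSE) {
  structure(list(freqs_hz = freqs_hz, power_db = power_db,
                 resolution_hz = resolution_hz, n_segments = n_segments,
                 normalized = normalized),
            class = "power_spectrum")
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# One-sided PSD of an already-tapered segment; norm = fs * sum(w^2).
onesided_psd <- function(segw, nfft, norm) {
  X <- stats::fft(c(segw, numeric(nfft - length(segw))))
  half <- nfft %/% 2
  P <- Mod(X[1:(half + 1)])^2 / norm
  P[2:half] <- 2 * P[2:half]
  if (nfft %% 2 == 1) P[half + 1] <- 2 * P[half + 1]
  P
}

# Average native-resolution PSD bins onto a coarser uniform grid.
regrid_psd <- function(P, native_res, res, fs) {
  freqs_nat <- (seq_along(P) - 1) * native_res
  fmax <- fs / 2
  freqs <- seq(0, fmax + 1e-9, by = res)
  idx <- pmin(length(freqs), floor((freqs_nat + res / 2) / res) + 1)
  Pm <- vapply(split(P, idx), mean, numeric(1))
  out <- numeric(length(freqs))
  out[as.integer(names(Pm))] <- Pm
  list(P = out, freqs = freqs)
}

#' Spectral band power (area under the linear PSD)
#'
#' Sums linear PSD bins with `lo <= f <= hi` (closed interval on the grid)
#' times the grid resolution, and reports `10*log10` of the area.
#'
#' @param spectrum A `power_spectrum`.
#' @param lo_hz,hi_hz Band edges in Hz.
#' @return An object of class `band_power` with fields `band`, `area_db`,
#'   `area_linear`, `normalized`.
#' @export
band_power <- function(spectrum, lo_hz, hi_hz) {
  if (!(lo_hz <= hi_hz)) stop("no bins in band: lo > hi")
  sel <- band_bins(spectrum$freqs_hz, lo_hz, hi_hz)
  if (!any(sel)) stop("no bins in band")
  area <- sum(10^(spectrum$power_db[sel] / 10)) * spectrum$resolution_hz
  structure(list(band = c(lo_hz, hi_hz), area_db = 10 * log10(area),
                 area_linear = area, normalized = isTRUE(spectrum$normalized)),
            class = "band_power")
}

band_bins <- function(freqs, lo, hi) {
  freqs >= lo - 1e-9 & freqs <= hi + 1e-9
}

#' Normalize a spectrum by its 1/f decay
#'
#' Divides the linear PSD by the mean linear power over a high-frequency
#' reference band (default 500-1000 Hz), i.e. subtracts a constant in dB, so
#' the mean normalized power over the reference band is 0 dB. All normalized
#' quantities are invariant to scalar gain applied to the raw signal.
#'
#' @param spectrum A `power_spectrum` extending to the reference band.
#' @param ref_band Two-element numeric, reference band in Hz.
#' @return The normalized `power_spectrum` (`normalized = TRUE`).
#' @export
normalize_1f <- function(spectrum, ref_band = c(500, 1000)) {
  if (max(spectrum$freqs_hz) < ref_band[2] - 1e-9)
    stop("reference band unavailable: spectrum does not cover ", ref_band[2], " Hz")
  sel <- band_bins(spectrum$freqs_hz, ref_band[1], ref_band[2])
  if (!any(sel)) stop("reference band unavailable")
  ref_db <- 10 * log10(mean(10^(spectrum$power_db[sel] / 10)))
  out <- spectrum
  out$power_db <- spectrum$power_db - ref_db
  out$normalized <- TRUE
  out
}

#' Peak frequency within a band
#'
#' Frequency of the maximum dB bin within the closed band; ties are broken
#' toward the lowest frequency.
#'
#' @param spectrum A `power_spectrum`.
#' @param band Two-element numeric band in Hz.
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(spectrum, band) {
  sel <- which(band_bins(spectrum$freqs_hz, band[1], band[2]))
  if (length(sel) == 0) stop("no bins in band")
  spectrum$freqs_hz[sel[which.max(spectrum$power_db[sel])]]
}

#' Select segments with clear theta activity
#'
#' Scores consecutive non-overlapping segments by the ratio of linear band
#' power in the theta (4-10 Hz) over the delta (1-4 Hz) band and returns the
#' start times of segments whose ratio exceeds the threshold.
#'
#' @param x Single-channel signal (microvolts).
#' @param fs Sampling rate in Hz.
#' @param segment_s Segment length in seconds (default 1).
#' @param ratio_threshold Theta/delta linear power ratio cut-off (default 2).
#' @param theta_band,delta_band Band definitions in Hz.
#' @return Numeric vector of segment start times in seconds (possibly empty).
#' @export
select_theta_segments <- function(x, fs, segment_s = 1, ratio_threshold = 2,
                                  theta_band = c(4, 10), delta_band = c(1, 4)) {
  nseg <- round(segment_s * fs)
  if (length(x) < nseg) stop("insufficient data: signal shorter than one segment")
  k <- floor(length(x) / nseg)
  w <- hamming_window(nseg)
  norm <- fs * sum(w^2)
  res <- fs / nseg
  freqs <- (seq_len(nseg %/% 2 + 1) - 1) * res
  th <- band_bins(freqs, theta_band[1], theta_band[2])
  de <- band_bins(freqs, delta_band[1], delta_band[2])
  starts <- numeric(0)
  for (i in seq_len(k)) {
    seg <- x[((i - 1) * nseg + 1):(i * nseg)]
    P <- onesided_psd((seg - mean(seg)) * w, nseg, norm)
    if (sum(P[th]) / sum(P[de]) > ratio_threshold)
      starts <- c(starts, (i - 1) * segment_s)
  }
  starts
}

#' Multitaper time-frequency map
#'
#' DPSS-tapered spectra averaged across tapers in sliding windows. At the
#' defaults (400 ms windows, 97.7% overlap) the hop is 9.2 ms. The per-window
#' spectrum is regridded to `resolution_hz` as in [average_spectrum()].
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 0.4).
#' @param overlap Fractional overlap of consecutive windows (default 0.977).
#' @param resolution_hz Output frequency grid step (default 10).
#' @param nw Time-bandwidth product (default 3).
#' @param k Number of tapers (default 5).
#' @return An object of class `tf_map` with `times_s` (window centres),
#'   `freqs_hz`, `power_db` (`[freq x time]`), and `hop_s`.
#' @export
multitaper_tfr <- function(x, fs, window_s = 0.4, overlap = 0.977,
                           resolution_hz = 10, nw = 3, k = 5) {
  win <- round(window_s * fs)
  if (length(x) < win) stop("insufficient data: window longer than signal")
  hop_s <- window_s * (1 - overlap)
  hop <- max(1L, round(hop_s * fs))
  tapers <- dpss_tapers(win, nw = nw, k = k)
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  nfft_req <- round(fs / resolution_hz)
  nfft <- max(win, nfft_req)
  native_res <- fs / nfft
  half <- nfft %/% 2
  pow <- NULL
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + win - 1L)]
    P <- numeric(half + 1)
    for (m in seq_len(k)) {
      P <- P + onesided_psd(seg * tapers[, m], nfft, fs)
    }
    P <- P / k
    if (nfft_req < win) {
      rg <- regrid_psd(P, native_res, resolution_hz, fs)
      P <- rg$P
      if (is.null(pow)) freqs <- rg$freqs
    } else if (is.null(pow)) {
      freqs <- (seq_along(P) - 1) * native_res
      resolution_hz <- native_res
    }
    if (is.null(pow)) pow <- matrix(0, nrow = length(P), ncol = length(starts))
    pow[, j] <- P
  }
  structure(list(times_s = (starts - 1 + win / 2) / fs, freqs_hz = freqs,
                 power_db = 10 * log10(pmax(pow, .Machine$double.xmin)),
                 hop_s = hop_s, window_s = window_s, overlap = overlap,
                 resolution_hz = resolution_hz),
            class = "tf_map")
}

# Multitaper spectrum of one window (helper used by the event featurizers):
# mean over tapers, regridded to resolution_hz.
multitaper_spectrum <- function(x, fs, resolution_hz = 10, nw = 3, k = 5) {
  tf <- multitaper_tfr(x, fs, window_s = length(x) / fs, overlap = 0,
                       resolution_hz = resolution_hz, nw = nw, k = k)
  new_power_spectrum(tf$freqs_hz, tf$power_db[, 1], tf$resolution_hz, 1L)
}

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the eigenvectors of the standard symmetric tridiagonal
#' matrix. For window lengths above 1024 samples the tapers are computed at
#' 1024 points and spline-interpolated to the full length, then renormalized
#' to unit energy; the approximation error is negligible for spectral
#' averaging. Results are cached per `(n, nw, k)`.
#'
#' @param n Window length in samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (`k <= 2*nw - 1` recommended).
#' @return An `n x k` matrix of unit-norm tapers.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  n_base <- min(n, 1024L)
  v <- dpss_exact(n_base, nw, k)
  if (n_base < n) {
    grid_in <- seq(0, 1, length.out = n_base)
    grid_out <- seq(0, 1, length.out = n)
    v <- apply(v, 2, function(col) {
      y <- stats::spline(grid_in, col, xout = grid_out)$y
      y / sqrt(sum(y^2))
    })
  }
  .taper_cache[[key]] <- v
  v
}

dpss_exact <- function(n, nw, k) {
  w <- nw / n
  i <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(i + 1, i + 1)] <- diag_v
  A[cbind(1:(n - 1), 2:n)] <- off_v
  A[cbind(2:n, 1:(n - 1))] <- off_v
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: positive mean (symmetric) or positive initial slope
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) < 1e-8) s <- v[2, j] - v[1, j]
    if (s < 0) v[, j] <- -v[, j]
  }
  v
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %g-%g Hz @ %g Hz, %d segments%s\n",
              min(x$freqs_hz), max(x$freqs_hz), x$resolution_hz, x$n_segments,
              if (isTRUE(x$normalized)) " (1/f normalized)" else ""))
  invisible(x)
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("<band_power> %g-%g Hz: %.3f dB%s\n", x$band[1], x$band[2],
              x$area_db, if (x$normalized) " (1/f normalized)" else ""))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, ...) {
  graphics::plot(x$freqs_hz, x$power_db, type = "l", xlab = "Frequency (Hz)",
                 ylab = if (isTRUE(x$normalized)) "Power (dB, 1/f normalized)"
                        else "Power (dB re 1 uV²/Hz)", ...)
  invisible(x)
}
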