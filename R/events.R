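#' Detector configuration for band-limited oscillatory events
#'
#' Both detectors follow the same pipeline: zero-phase band-pass, rectify,
#' Savitzky-Golay smooth, z-score over the full analysis epoch, detect
#' candidates above `detect_z` (2.5 SD), then delimit each event by the
#' contiguous region where the Hilbert envelope of the band-passed signal
#' exceeds `duration_z` (1.6 robust SD units; the envelope is z-scored with
#' median/MAD so that the boundary threshold stays calibrated to the
#' background when events occupy a noticeable fraction of the epoch). Events closer than `merge_gap_ms` are
#' merged and events shorter than `min_duration_ms` discarded.
#'
#' @param band A [filter_spec()] giving the detection band.
#' @param detect_z Detection threshold in SD units (default 2.5).
#' @param duration_z Boundary threshold on the envelope (default 1.6,
#'   must be below `detect_z`).
#' @param min_duration_ms Minimum event duration.
#' @param merge_gap_ms Events with gaps below this are merged.
#' @param smooth_window_ms,smooth_polyorder Savitzky-Golay settings.
#' @param type Event label used in the output table.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(band, detect_z = 2.5, duration_z = 1.6,
                            min_duration_ms = 20, merge_gap_ms = 30,
                            smooth_window_ms = 5, smooth_polyorder = 3,
                            type = "ripple") {
  if (!inherits(band, "filter_spec")) stop("band must be a filter_spec")
  if (!(duration_z < detect_z)) stop("duration_z must be below detect_z")
  if (min_duration_ms < 0) stop("min_duration_ms must be >= 0")
  structure(list(band = band, detect_z = detect_z, duration_z = duration_z,
                 min_duration_ms = min_duration_ms, merge_gap_ms = merge_gap_ms,
                 smooth_window_ms = smooth_window_ms,
                 smooth_polyorder = smooth_polyorder, type = type),
            class = "detector_config")
}

#' Default ripple detector configuration
#'
#' 100-600 Hz band-pass of order 512 designed on a 10 Hz grid; ripples are
#' analyzed as 100-250 Hz phenomena but detected on the wide band.
#' @param ... Overrides passed to [detector_config()].
#' @export
ripple_config <- function(...) {
  args <- list(band = filter_spec(100, 600, order = 512, design_resolution_hz = 10),
               min_duration_ms = 20, merge_gap_ms = 30, type = "ripple")
  override <- list(...)
  args[names(override)] <- override
  do.call(detector_config, args)
}

#' Default sleep-spindle detector configuration
#'
#' 7-16 Hz band-pass of order 512 designed on a 0.5 Hz grid; smoothing
#' window widened to 100 ms to match the slower band.
#' @param ... Overrides passed to [detector_config()].
#' @export
spindle_config <- function(...) {
  args <- list(band = filter_spec(7, 16, order = 512, design_resolution_hz = 0.5),
               min_duration_ms = 300, merge_gap_ms = 300,
               smooth_window_ms = 100, type = "spindle")
  override <- list(...)
  args[names(override)] <- override
  do.call(detector_config, args)
}

#' Detect band-limited events by thresholding
#'
#' Runs the rectified/smoothed z-score detection pipeline (see
#' [detector_config()]) on a single channel and returns an [event_table()].
#'
#' @param x Single-channel signal in microvolts (the full analysis epoch;
#'   mean and SD for z-scoring are taken over all of it).
#' @param fs Sampling rate in Hz.
#' @param config A [detector_config()].
#' @param channel Channel index recorded in the output (default `NA`).
#' @param t0_s Time of the first sample (event times are absolute).
#' @return An [event_table()] with one row per event.
#' @export
detect_band_events <- function(x, fs, config, channel = NA_integer_, t0_s = 0) {
  band_period_s <- 1 / config$band$band_lo_hz
  if (length(x) / fs < 10 * band_period_s) stop("epoch too short")
  bp <- bandpass_zerophase(x, fs, config$band)
  sm <- savgol_smooth(abs(bp), fs, window_ms = config$smooth_window_ms,
                      polyorder = config$smooth_polyorder)
  s_sd <- stats::sd(sm)
  if (!(s_sd > 0)) stop("degenerate signal: zero variance after smoothing")
  z <- (sm - mean(sm)) / s_sd
  rm(sm)
  # robust z for the boundary statistic: with event duty cycles of a few
  # percent the plain SD of the envelope is inflated by the events
  # themselves, which would truncate measured durations; median/MAD stay
  # calibrated to the background (for Gaussian background MAD*1.4826 ~ SD)
  env <- hilbert_envelope(bp)
  rm(bp)
  ze <- (env - stats::median(env)) / stats::mad(env)
  rm(env); gc(FALSE)

  above <- z > config$detect_z
  if (!any(above)) return(empty_event_table(config$type))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand_peaks <- mapply(function(s, e) s - 1L + which.max(z[s:e]),
                       starts[r$values], ends[r$values])

  sup <- ze > config$duration_z
  rs <- rle(sup)
  rende <- cumsum(rs$lengths)
  rstart <- rende - rs$lengths + 1L
  reg_start <- rstart[rs$values]; reg_end <- rende[rs$values]
  # boundaries = the contiguous supra-duration_z envelope region containing
  # the candidate peak; a candidate whose peak lies in no such region has
  # no delimitable extent and is dropped
  reg_of <- findInterval(cand_peaks, reg_start)
  ev <- lapply(seq_along(cand_peaks), function(i) {
    k <- reg_of[i]
    if (k >= 1 && cand_peaks[i] <= reg_end[k])
      c(reg_start[k], cand_peaks[i], reg_end[k])
    else NULL
  })
  ev <- unique(Filter(Negate(is.null), ev))
  if (length(ev) == 0) return(empty_event_table(config$type))
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev[, 1]), , drop = FALSE]

  # discard candidates whose own envelope region is shorter than
  # min_duration BEFORE merging: merging exists to consolidate nearby
  # detections of one event, and filtering after merging would let chains
  # of millisecond noise excursions bridge into long pseudo-events
  keep <- (ev[, 3] - ev[, 1] + 1) / fs * 1000 >= config$min_duration_ms
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0) return(empty_event_table(config$type))

  gap_n <- config$merge_gap_ms / 1000 * fs
  merged <- list()
  cur <- ev[1, ]
  for (i in seq_len(nrow(ev))[-1]) {
    if (ev[i, 1] - cur[3] < gap_n) {
      cur[3] <- max(cur[3], ev[i, 3])
      if (z[ev[i, 2]] > z[cur[2]]) cur[2] <- ev[i, 2]
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- ev[i, ]
    }
  }
  merged[[length(merged) + 1]] <- cur
  m <- do.call(rbind, merged)
  if (nrow(m) == 0) return(empty_event_table(config$type))
  event_table(data.frame(
    type = config$type, channel = channel,
    t_start_s = t0_s + (m[, 1] - 1) / fs,
    t_peak_s = t0_s + (m[, 2] - 1) / fs,
    t_end_s = t0_s + (m[, 3] - 1) / fs,
    duration_ms = (m[, 3] - m[, 1] + 1) / fs * 1000,
    peak_z = z[m[, 2]],
    stringsAsFactors = FALSE))
}

empty_event_table <- function(type) {
  event_table(data.frame(type = character(0), channel = integer(0),
                         t_start_s = numeric(0), t_peak_s = numeric(0),
                         t_end_s = numeric(0), duration_ms = numeric(0),
                         peak_z = numeric(0), stringsAsFactors = FALSE))
}

#' Per-event ripple features
#'
#' For each detected ripple: duration from the detection step; event power
#' as the mean multitaper power in 100-300 Hz over a +/-200 ms window
#' centred at the peak; peak frequency of that window's spectrum; the
#' associated sharp-wave amplitude measured baseline-to-trough on the
#' stratum radiatum channel within +/-50 ms of the peak (the radiatum trace
#' is Savitzky-Golay smoothed first so the trough is read on the slow
#' deflection, not on ripple-band noise); and the table-level occurrence
#' rate. Events whose window would extend past the recording edge are
#' flagged `"edge"` and computed on the available samples.
#'
#' @param rec A [laminar_recording()].
#' @param events [event_table()] of ripples detected on `pyr_channel`.
#' @param pyr_channel,rad_channel Channel indices of stratum pyramidale and
#'   radiatum.
#' @param power_band Band for event power/peak frequency (default 100-300 Hz).
#' @param half_win_s Half-width of the spectral window (default 0.2 s).
#' @return A data.frame of class `ripple_features` (one row per event) with
#'   attribute `rate_hz`.
#' @export
characterize_ripples <- function(rec, events, pyr_channel, rad_channel,
                                 power_band = c(100, 300), half_win_s = 0.2) {
  fs <- rec$fs
  n <- ncol(rec$samples)
  hw <- round(half_win_s * fs)
  x_pyr <- rec$samples[pyr_channel, ]
  x_rad <- savgol_smooth(rec$samples[rad_channel, ], fs, window_ms = 15,
                         polyorder = 3)
  sw_hw <- round(0.05 * fs)
  base_in <- round(0.06 * fs)
  base_out <- round(0.09 * fs)
  out <- data.frame(duration_ms = events$duration_ms,
                    power_db = NA_real_, peak_freq_hz = NA_real_,
                    sw_amplitude_uv = NA_real_, edge = FALSE)
  for (i in seq_len(nrow(events))) {
    ip <- round((events$t_peak_s[i] - rec$t0_s) * fs) + 1L
    i0 <- ip - hw; i1 <- ip + hw
    if (i0 < 1 || i1 > n) {
      out$edge[i] <- TRUE
      i0 <- max(1L, i0); i1 <- min(n, i1)
    }
    sp <- multitaper_spectrum(x_pyr[i0:i1], fs, resolution_hz = 10)
    sel <- band_bins(sp$freqs_hz, power_band[1], power_band[2])
    out$power_db[i] <- mean(sp$power_db[sel])
    out$peak_freq_hz[i] <- peak_frequency(sp, power_band)
    # sharp wave at radiatum: baseline interpolated between the two
    # 60-90 ms flanks, detrending the slow LIA activity the event rides on
    lf <- seq(max(1L, ip - base_out), max(1L, ip - base_in))
    rf <- seq(min(n, ip + base_in), min(n, ip + base_out))
    s0 <- max(1L, ip - sw_hw); s1 <- min(n, ip + sw_hw)
    itr <- (s0:s1)[which.min(x_rad[s0:s1])]
    base <- mean(x_rad[lf]) +
      (mean(x_rad[rf]) - mean(x_rad[lf])) *
        (itr - mean(lf)) / (mean(rf) - mean(lf))
    out$sw_amplitude_uv[i] <- base - x_rad[itr]
  }
  attr(out, "rate_hz") <- nrow(events) / (n / fs)
  class(out) <- c("ripple_features", "data.frame")
  out
}

#' Per-event spindle features
#'
#' Duration from the envelope step of the detector; spindle power as the
#' mean multitaper power in 10-16 Hz over a window centred at the peak (the
#' paper's convention: power band 10-16 Hz even though detection runs at
#' 7-16 Hz); and the inter-spindle interval `t_start(k+1) - t_end(k)`
#' between consecutive spindles of the same epoch (NA for the last or a
#' lone spindle).
#'
#' @param eeg An [eeg_recording()] (SWS epochs).
#' @param events [event_table()] of detected spindles.
#' @param power_band Band for spindle power (default 10-16 Hz).
#' @param win_s Spectral window length in seconds (default 1).
#' @return A data.frame of class `spindle_features`.
#' @export
characterize_spindles <- function(eeg, events, power_band = c(10, 16),
                                  win_s = 1) {
  fs <- eeg$fs
  x <- eeg$trace
  n <- length(x)
  hw <- round(win_s * fs / 2)
  out <- data.frame(duration_ms = events$duration_ms, power_db = NA_real_,
                    isi_s = NA_real_, edge = FALSE)
  for (i in seq_len(nrow(events))) {
    ip <- round((events$t_peak_s[i] - eeg$t0_s) * fs) + 1L
    i0 <- ip - hw; i1 <- ip + hw
    if (i0 < 1 || i1 > n) { out$edge[i] <- TRUE; i0 <- max(1L, i0); i1 <- min(n, i1) }
    sp <- multitaper_spectrum(x[i0:i1], fs, resolution_hz = 1, nw = 2, k = 3)
    sel <- band_bins(sp$freqs_hz, power_band[1], power_band[2])
    out$power_db[i] <- mean(sp$power_db[sel])
  }
  if (nrow(events) > 1) {
    epoch_of <- epoch_index(eeg$epochs, events$t_peak_s)
    for (i in seq_len(nrow(events) - 1)) {
      if (is.na(epoch_of[i]) || identical(epoch_of[i], epoch_of[i + 1]))
        out$isi_s[i] <- events$t_start_s[i + 1] - events$t_end_s[i]
    }
  }
  class(out) <- c("spindle_features", "data.frame")
  out
}

epoch_index <- function(epochs, times) {
  if (is.null(epochs)) return(rep(NA_integer_, length(times)))
  vapply(times, function(tt) {
    k <- which(epochs$t_start_s <= tt & tt < epochs$t_end_s)
    if (length(k) == 1) k else NA_integer_
  }, integer(1))
}

#' Match detections against ground-truth events
#'
#' One-to-one interval matching: a detection matches a true event when the
#' detected interval overlaps the true interval padded by `tol_s`; among
#' competing pairs, closest peaks win. Returns sensitivity (recall),
#' precision and the index pairing.
#'
#' @param detected,truth Data frames with `t_start_s`, `t_peak_s`, `t_end_s`.
#' @param tol_s Matching tolerance in seconds (0.01 for ripples, 0.1 for
#'   spindles).
#' @return List with `sensitivity`, `precision`, `n_matched`, and a
#'   two-column matrix `pairs` (detected row, truth row).
#' @export
match_events <- function(detected, truth, tol_s = 0.01) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(sensitivity = 0, precision = if (nd == 0) NA_real_ else 0,
                n_matched = 0L, pairs = matrix(integer(0), ncol = 2)))
  }
  cand <- NULL
  for (i in seq_len(nd)) {
    ov <- which(detected$t_start_s[i] <= truth$t_end_s + tol_s &
                  detected$t_end_s[i] >= truth$t_start_s - tol_s)
    if (length(ov) > 0)
      cand <- rbind(cand, cbind(i, ov,
                                abs(detected$t_peak_s[i] - truth$t_peak_s[ov])))
  }
  pairs <- matrix(integer(0), ncol = 2)
  if (!is.null(cand)) {
    cand <- cand[order(cand[, 3]), , drop = FALSE]
    used_d <- logical(nd); used_t <- logical(nt)
    for (row in seq_len(nrow(cand))) {
      i <- cand[row, 1]; j <- cand[row, 2]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- TRUE; used_t[j] <- TRUE
        pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  m <- nrow(pairs)
  list(sensitivity = m / nt, precision = m / nd, n_matched = m, pairs = pairs)
}
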