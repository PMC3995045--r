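#' Stimulus-locked evoked sweep
#'
#' @param trace Numeric vector in microvolts.
#' @param fs Sampling rate in Hz.
#' @param stim_sample Sample index of stimulus onset (1-based).
#' @param intensity_ua Stimulus intensity in microamperes.
#' @param site Recording site label, `"radiatum"` or `"pyramidale"`.
#' @return An object of class `evoked_sweep`. Requires at least 5 ms of
#'   pre-stimulus baseline.
#' @export
evoked_sweep <- function(trace, fs, stim_sample, intensity_ua,
                         site = c("radiatum", "pyramidale")) {
  site <- match.arg(site)
  if ((stim_sample - 1) / fs < 0.005)
    stop("sweep lacking 5 ms pre-stimulus baseline")
  structure(list(trace = as.numeric(trace), fs = fs,
                 stim_sample = as.integer(stim_sample),
                 intensity_ua = intensity_ua, site = site),
            class = "evoked_sweep")
}

default_windows <- function() {
  list(av = c(1, 4), fepsp = c(3, 30), ps = c(4, 15))  # ms post-stimulus
}

#' Measure an evoked sweep
#'
#' Baseline is the mean of the 5 ms preceding the stimulus. The fEPSP
#' amplitude is baseline-to-extremum in the fEPSP window; its slope is the
#' least-squares slope over the 20-80% amplitude span of the initial falling
#' phase (avoiding population-spike contamination). The afferent-volley
#' amplitude is the first negative deflection in the AV window. The
#' population-spike amplitude is the trough depth below the chord joining
#' the flanking positive peaks; when no flanking local maxima exist within
#' 3 ms of the trough (no spike), it is 0.
#'
#' @param sweep An [evoked_sweep()], or a numeric trace together with `fs`
#'   and `stim_sample`.
#' @param windows List with elements `av`, `fepsp`, `ps`, each `c(lo, hi)`
#'   in ms post-stimulus.
#' @param smooth_ms Savitzky-Golay window applied before amplitude reading
#'   (0 disables smoothing).
#' @return An object of class `evoked_measures`: `av_amplitude_uv`,
#'   `fepsp_amplitude_uv`, `fepsp_slope_uv_ms` (signed), `ps_amplitude_uv`,
#'   `baseline_uv`, `noise_sd_uv`.
#' @export
measure_evoked <- function(sweep, windows = default_windows(), smooth_ms = 1) {
  tr <- sweep$trace; fs <- sweep$fs; s0 <- sweep$stim_sample
  nb <- round(0.005 * fs)
  if (s0 - nb < 1) stop("sweep lacking 5 ms pre-stimulus baseline")
  base_idx <- (s0 - nb):(s0 - 1)
  baseline <- mean(tr[base_idx])
  noise_sd <- stats::sd(tr[base_idx])
  trs <- if (smooth_ms > 0 && length(tr) > round(smooth_ms * fs / 1000) + 4)
    savgol_smooth(tr, fs, window_ms = smooth_ms, polyorder = 3) else tr

  win_idx <- function(w) {
    i0 <- s0 + round(w[1] / 1000 * fs); i1 <- s0 + round(w[2] / 1000 * fs)
    if (i0 < 1 || i1 > length(tr) || i1 <= i0) stop("window contaminated: outside sweep")
    i0:i1
  }

  # afferent volley: first local minimum in the AV window
  avi <- win_idx(windows$av)
  av_seg <- trs[avi]
  mins <- which(diff(sign(diff(av_seg))) > 0) + 1L
  av_amp <- if (length(mins) > 0) baseline - av_seg[mins[1]] else
    baseline - min(av_seg)

  # fEPSP amplitude and slope
  fi <- win_idx(windows$fepsp)
  fseg <- trs[fi]
  imin <- which.min(fseg)
  amp <- baseline - fseg[imin]
  # span levels for the slope come from a median-filtered amplitude so a
  # narrow population spike does not stretch the 20-80% span (the initial
  # falling phase must stay uncontaminated)
  kmed <- round(0.003 * fs); if (kmed %% 2 == 0) kmed <- kmed + 1
  amp_s <- if (length(fseg) > kmed && kmed >= 3)
    baseline - min(stats::runmed(fseg, kmed)) else amp
  slope <- 0
  if (amp_s > 0 && imin > 2) {
    lev20 <- baseline - 0.2 * amp_s
    lev80 <- baseline - 0.8 * amp_s
    # crossing times read on a more heavily smoothed copy to suppress
    # first-passage bias; the slope itself is fitted on `trs`
    trc <- if (length(tr) > round(0.002 * fs) + 4)
      savgol_smooth(tr, fs, window_ms = 2, polyorder = 3) else trs
    onset <- fi[1:imin]
    below20 <- which(trc[onset] <= lev20)
    below80 <- which(trc[onset] <= lev80)
    if (length(below20) > 0 && length(below80) > 0) {
      i20 <- below20[1]; i80 <- below80[1]
      if (i80 > i20) {
        span <- onset[i20:i80]
        tt <- (span - s0) / fs * 1000
        slope <- stats::coef(stats::lm(trs[span] ~ tt))[[2]]
      }
    }
  }

  # population spike: chord method around the sharpest trough in the PS window
  pi_ <- win_idx(windows$ps)
  pseg <- trs[pi_]
  itr <- which.min(pseg)
  guard <- round(0.003 * fs)
  left <- pseg[max(1, itr - guard):max(1, itr - 1)]
  right <- pseg[min(length(pseg), itr + 1):min(length(pseg), itr + guard)]
  lmax <- local_maxima(left); rmax <- local_maxima(right)
  ps_amp <- 0
  if (length(lmax) > 0 && length(rmax) > 0) {
    iL <- max(1, itr - guard) - 1 + lmax[length(lmax)]
    iR <- min(length(pseg), itr + 1) - 1 + rmax[1]
    chord <- pseg[iL] + (pseg[iR] - pseg[iL]) * (itr - iL) / (iR - iL)
    ps_amp <- max(0, chord - pseg[itr])
  } else if (length(lmax) > 0 || length(rmax) > 0) {
    # one flanking positivity only (the other swamped by the fEPSP limb):
    # fall back to the one-sided level, as in the tangent method
    iF <- if (length(rmax) > 0) min(length(pseg), itr + 1) - 1 + rmax[1] else
      max(1, itr - guard) - 1 + lmax[length(lmax)]
    ps_amp <- max(0, pseg[iF] - pseg[itr])
  }

  structure(list(av_amplitude_uv = av_amp, fepsp_amplitude_uv = amp,
                 fepsp_slope_uv_ms = slope, ps_amplitude_uv = ps_amp,
                 baseline_uv = baseline, noise_sd_uv = noise_sd),
            class = "evoked_measures")
}

local_maxima <- function(x) {
  if (length(x) < 3) return(integer(0))
  which(diff(sign(diff(x))) < 0) + 1L
}

#' Average sweeps of equal intensity
#'
#' @param sweeps List of [evoked_sweep()] at one intensity (same geometry).
#' @return One [evoked_sweep()] with the mean trace.
#' @export
average_sweeps <- function(sweeps) {
  tr <- rowMeans(vapply(sweeps, function(s) s$trace,
                        numeric(length(sweeps[[1]]$trace))))
  s1 <- sweeps[[1]]
  evoked_sweep(tr, s1$fs, s1$stim_sample, s1$intensity_ua, s1$site)
}

#' Build an input/output curve
#'
#' Sweeps are grouped by intensity, averaged, measured, and sorted by
#' ascending intensity.
#'
#' @param sweeps List of [evoked_sweep()] covering >= 2 intensities.
#' @param windows Measurement windows, see [measure_evoked()].
#' @return An object of class `io_curve`: data.frame with `intensity_ua`,
#'   `av_amplitude_uv`, `fepsp_amplitude_uv`, `fepsp_slope_uv_ms`,
#'   `ps_amplitude_uv`, `n_sweeps`, `noise_sd_uv`.
#' @export
build_io_curve <- function(sweeps, windows = default_windows()) {
  ints <- vapply(sweeps, function(s) s$intensity_ua, numeric(1))
  levels <- sort(unique(ints))
  if (length(levels) < 2) stop("insufficient input/output data: need >= 2 intensities")
  rows <- lapply(levels, function(I) {
    grp <- sweeps[ints == I]
    m <- measure_evoked(average_sweeps(grp), windows)
    data.frame(intensity_ua = I, av_amplitude_uv = m$av_amplitude_uv,
               fepsp_amplitude_uv = m$fepsp_amplitude_uv,
               fepsp_slope_uv_ms = m$fepsp_slope_uv_ms,
               ps_amplitude_uv = m$ps_amplitude_uv,
               n_sweeps = length(grp), noise_sd_uv = m$noise_sd_uv)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("io_curve", "data.frame")
  out
}

#' Population-spike threshold from an input/output curve
#'
#' Lowest tested intensity whose population-spike amplitude exceeds
#' `3 * noise_sd`; `"not reached"` when none does.
#'
#' @param io_curve An [build_io_curve()] result.
#' @param noise_sd Pre-stimulus noise SD in microvolts (of the measured,
#'   typically averaged, trace).
#' @return Intensity in microamperes, or the string `"not reached"`.
#' @export
population_spike_threshold <- function(io_curve, noise_sd) {
  hit <- which(io_curve$ps_amplitude_uv > 3 * noise_sd)
  if (length(hit) == 0) return("not reached")
  io_curve$intensity_ua[hit[1]]
}

#' Paired-pulse ratios
#'
#' Each pair holds two pulses at one inter-pulse interval; the ratio is the
#' second-response measure over the first, using the same measurement rule
#' for both pulses, with the second-pulse windows offset by the interval and
#' the pre-first-pulse baseline reused (the inter-pulse interval may not
#' return to rest). Facilitation is probed at 40% of the maximal-response
#' intensity, inhibition at maximal intensity.
#'
#' @param sweep_pairs List of [evoked_sweep()]s each containing both pulses
#'   (`stim_sample` marks the first pulse), with attribute or list element
#'   `interval_ms` per sweep.
#' @param intervals_ms Inter-pulse intervals (ms) to report, default
#'   `c(25, 50, 75, 100, 125, 150)`.
#' @param measure Which measure forms the ratio: `"fepsp_amplitude_uv"`
#'   (default) or `"fepsp_slope_uv_ms"`.
#' @param windows First-pulse measurement windows.
#' @param mode Label stored in the result (`"facilitation"` or `"inhibition"`).
#' @return Data.frame of class `pp_result`: `interval_ms`, `ratio`,
#'   `first`, `second`, `defined`.
#' @export
paired_pulse_ratios <- function(sweep_pairs, intervals_ms = c(25, 50, 75, 100, 125, 150),
                                measure = "fepsp_amplitude_uv",
                                windows = default_windows(),
                                mode = "facilitation") {
  pair_int <- vapply(sweep_pairs, function(s) s$interval_ms, numeric(1))
  rows <- lapply(intervals_ms, function(iv) {
    grp <- sweep_pairs[abs(pair_int - iv) < 1e-9]
    if (length(grp) == 0)
      return(data.frame(interval_ms = iv, ratio = NA_real_, first = NA_real_,
                        second = NA_real_, defined = FALSE))
    avg <- average_sweeps(grp)
    m1 <- measure_evoked(avg, windows)
    w2 <- lapply(windows, function(w) w + iv)
    m2 <- measure_evoked(avg, w2)
    v1 <- m1[[measure]]; v2 <- m2[[measure]]
    ok <- abs(v1) > 3 * m1$noise_sd_uv
    data.frame(interval_ms = iv, ratio = if (ok) v2 / v1 else NA_real_,
               first = v1, second = v2, defined = ok)
  })
  out <- do.call(rbind, rows)
  out$mode <- mode
  class(out) <- c("pp_result", "data.frame")
  out
}
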