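#' Simulation configuration
#'
#' Seeded forward model of urethane-like hippocampal activity and chronic
#' EEG used for detector benchmarking. Sections are lists merged over the
#' defaults, so `sim_config(ripples = list(n_events = 80))` overrides one
#' field and keeps the rest.
#'
#' Default phenomenology: per-channel 1/f background; theta (5 Hz) with
#' amplitude maximal at stratum lacunosum-moleculare and a 180-degree phase
#' step between the pyramidale and slm sides of the probe; theta-modulated
#' gamma (40 Hz); sharp-wave-ripple events during LIA epochs (150 Hz burst
#' maximal at pyramidale plus a negative Gaussian sharp wave, sigma 25 ms,
#' maximal at radiatum); MUA at the cell-body layers; and, for the EEG
#' model, SWS slow oscillation with K-complexes coupled to sleep spindles.
#'
#' Event bursts use a flat-topped raised-cosine (Tukey) envelope with taper
#' fraction `taper`; the ground-truth duration is the full envelope extent,
#' which is well-defined against threshold-based duration estimates because
#' onset and offset are fast relative to the event length.
#'
#' Burst amplitudes are calibrated in envelope z units: from the synthesis
#' gains the generator knows the band-limited noise RMS `sigma_b` exactly,
#' and the Hilbert envelope of band-passed Gaussian noise is Rayleigh with
#' mean `1.2533 sigma_b` and SD `0.6551 sigma_b`, so a target envelope
#' z-score maps to a deterministic peak amplitude.
#'
#' @param seed Integer RNG seed; recorded in every output's metadata.
#' @param duration_s,fs Recording duration (s) and sampling rate (Hz).
#' @param n_channels,spacing_um Probe geometry.
#' @param noise List: `exponent` (1/f^a, default 1), `scale_uv` (total RMS).
#' @param theta List: `freq_hz`, `amp_uv` (at slm), `width_ch`,
#'   `freq_jitter_hz`, `amp_mod`, `lia_gain`.
#' @param gamma List: `freq_hz`, `amp_uv`, `mod_depth`.
#' @param ripples List: `rate_hz`, `n_events` (overrides rate), `freq_hz`,
#'   `duration_ms`, `amp_z` (range), `taper`, `width_ch`, `min_gap_s`.
#' @param sharp_wave List: `amp_uv`, `sigma_ms`, `width_ch`.
#' @param lia List: `delta_amp_uv` (RMS of the large irregular slow activity
#'   present during LIA epochs), `band_hz`.
#' @param mua List: `rate_hz`, `amp_uv`, `width_ch`.
#' @param layers List of ground-truth channels: `pyramidale`, `radiatum`,
#'   `slm`, `granule`; `NULL` picks defaults scaled to the probe.
#' @param epochs An [epoch_table()] state schedule; `NULL` alternates
#'   theta/LIA blocks.
#' @param eeg List of EEG-model settings (see Details in the source):
#'   spindle count/frequency/duration/amplitude, K-complex shape and
#'   coupling probability, slow-oscillation and REM-theta amplitudes.
#' @param evoked List of evoked-model settings: intensity grid, sweeps per
#'   intensity, sigmoid input/output parameters, population-spike threshold,
#'   paired-pulse factors, SNR.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, duration_s = 60, fs = 20000,
                       n_channels = 32, spacing_um = 25,
                       noise = list(), theta = list(), gamma = list(),
                       ripples = list(), sharp_wave = list(), lia = list(),
                       mua = list(), layers = NULL, epochs = NULL,
                       eeg = list(), evoked = list()) {
  cfg <- list(
    seed = as.integer(seed), duration_s = duration_s, fs = fs,
    n_channels = as.integer(n_channels), spacing_um = spacing_um,
    noise = merge_defaults(list(exponent = 1, scale_uv = 30), noise),
    theta = merge_defaults(list(freq_hz = 5, amp_uv = 200, width_ch = 3,
                                freq_jitter_hz = 0.3, amp_mod = 0.2,
                                lia_gain = 0.1), theta),
    gamma = merge_defaults(list(freq_hz = 40, amp_uv = 25, mod_depth = 0.8),
                           gamma),
    ripples = merge_defaults(list(rate_hz = 0.4, n_events = NULL,
                                  freq_hz = 150, duration_ms = 60,
                                  amp_z = c(5, 8), taper = 0.15,
                                  width_ch = 1.2, min_gap_s = 0.5), ripples),
    sharp_wave = merge_defaults(list(amp_uv = 300, sigma_ms = 25,
                                     width_ch = 2), sharp_wave),
    lia = merge_defaults(list(delta_amp_uv = 40, band_hz = c(0.5, 4)), lia),
    mua = merge_defaults(list(rate_hz = 50, amp_uv = 200, width_ch = 0.8), mua),
    layers = layers, epochs = epochs,
    eeg = merge_defaults(list(n_spindles = 60, spindle_freq_hz = 12,
                              spindle_duration_ms = 800, spindle_amp_z = 6,
                              spindle_taper = 0.1, spindle_min_gap_s = 2,
                              kc_prob = 0.7, kc_amp_uv = 250, kc_sigma_ms = 80,
                              slow_freq_hz = 1, slow_amp_uv = 100,
                              rem_theta_hz = 6.5, rem_theta_uv = 50), eeg),
    evoked = merge_defaults(list(intensities_ua = seq(25, 900, length.out = 8),
                                 n_sweeps = 10, fs = 20000, snr = 10,
                                 fepsp_amp_max_uv = 1200, io_i50_ua = 300,
                                 io_slope_ua = 90, fepsp_latency_ms = 3,
                                 fepsp_tau_ms = 4, av_amp_max_uv = 120,
                                 av_i_half_ua = 300, av_latency_ms = 1.5,
                                 ps_threshold_ua = 400, ps_amp_max_uv = 800,
                                 ps_sigma_ms = 0.6,
                                 pp_intervals_ms = c(25, 50, 75, 100, 125, 150),
                                 pp_facilitation = c(1.2, 1.4, 1.3, 1.2, 1.15, 1.1),
                                 pp_inhibition = c(0.5, 0.6, 0.7, 0.8, 0.85, 0.9),
                                 pp_fac_intensity_ua = 360), evoked))
  if (is.null(cfg$layers)) cfg$layers <- default_layer_channels(cfg$n_channels)
  if (cfg$ripples$rate_hz < 0 || cfg$eeg$n_spindles < 0) stop("rates must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

merge_defaults <- function(defaults, override) {
  bad <- setdiff(names(override), names(defaults))
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  defaults[names(override)] <- override
  defaults
}

default_layer_channels <- function(n) {
  cand <- pmax(1L, pmin(n, round(c(0.16, 0.28, 0.44, 0.75) * n)))
  for (i in 2:4) cand[i] <- min(n, max(cand[i], cand[i - 1] + 1L))
  list(pyramidale = cand[1], radiatum = cand[2], slm = cand[3],
       granule = cand[4])
}

default_state_schedule <- function(duration_s, block_s = 30) {
  block_s <- min(block_s, duration_s / 2)
  starts <- seq(0, duration_s - 1e-9, by = block_s)
  epoch_table(label = rep(c("theta", "LIA"), length.out = length(starts)),
              t_start_s = starts,
              t_end_s = pmin(starts + block_s, duration_s))
}

# flat-topped raised-cosine window; taper = fraction of length in each ramp
tukey_window <- function(n, taper = 0.15) {
  w <- rep(1, n)
  m <- max(1L, round(taper * n))
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = m)))
  w[1:m] <- ramp
  w[(n - m + 1):n] <- rev(ramp)
  w
}

# two-sided synthesis gains for 1/f^a noise of total RMS scale_uv;
# flat below 1 Hz, zero at DC
onef_gains <- function(n, fs, exponent, scale_uv) {
  k <- 0:(n - 1)
  fabs <- pmin(k, n - k) * fs / n
  g <- 1 / pmax(fabs, 1)^(exponent / 2)
  g[1] <- 0
  v <- sum(g^2) / n^2
  g * scale_uv / sqrt(v)
}

onef_noise_from_gains <- function(g) {
  onef_noise_pair(g)[[1]]
}

# one complex inverse FFT yields two independent real noise traces: with a
# frequency-symmetric gain spectrum and circularly symmetric coefficients
# the real and imaginary parts are jointly Gaussian with zero cross-
# covariance and identical PSDs
onef_noise_pair <- function(g) {
  n <- length(g)
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  z <- g * z
  if (n > 5e6) gc(FALSE)
  y <- stats::fft(z, inverse = TRUE) / n
  rm(z)
  out <- list(Re(y), Im(y))
  rm(y)
  if (n > 5e6) gc(FALSE)
  out
}

# analytic band RMS implied by synthesis gains (both spectral sides)
gain_band_rms <- function(g, fs, lo, hi) {
  n <- length(g)
  fabs <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  sel <- fabs >= lo & fabs <= hi
  sqrt(sum(g[sel]^2) / n^2)
}

# Rayleigh envelope statistics: peak amplitude for a target envelope z-score
amp_for_envelope_z <- function(z, sigma_b) {
  (sqrt(pi / 2) + z * sqrt(2 - pi / 2)) * sigma_b
}

# place n event times inside epochs with a minimum gap and edge padding
place_event_times <- function(n, epochs, min_gap_s, edge_pad_s) {
  iv <- cbind(epochs$t_start_s + edge_pad_s, epochs$t_end_s - edge_pad_s)
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  if (nrow(iv) == 0 || n == 0) return(numeric(0))
  len <- iv[, 2] - iv[, 1]
  total <- sum(len)
  times <- numeric(0)
  tries <- 0L
  while (length(times) < n && tries < 200L * n) {
    u <- stats::runif(1, 0, total)
    j <- findInterval(u, cumsum(c(0, len)), rightmost.closed = TRUE)
    tt <- iv[j, 1] + (u - cumsum(c(0, len))[j])
    if (all(abs(times - tt) >= min_gap_s)) times <- c(times, tt)
    tries <- tries + 1L
  }
  sort(times)
}

state_gain_vector <- function(epochs, n, fs, theta_states, gain_low) {
  gain <- rep(gain_low, n)
  for (i in seq_len(nrow(epochs))) {
    if (epochs$label[i] %in% theta_states) {
      i0 <- max(1L, round(epochs$t_start_s[i] * fs) + 1L)
      i1 <- min(n, round(epochs$t_end_s[i] * fs))
      if (i1 >= i0) gain[i0:i1] <- 1
    }
  }
  gain
}

ar1_noise <- function(n, tau_s, fs) {
  a <- exp(-1 / (fs * tau_s))
  x <- stats::filter(stats::rnorm(n), a, method = "recursive")
  as.numeric(x) * sqrt(1 - a^2)
}

#' Generate a laminar LFP scene with ground truth
#'
#' Deterministic given the config seed: identical configs produce
#' bit-identical recordings and truth tables.
#'
#' @param config A [sim_config()].
#' @return List with `recording` (a [laminar_recording()]) and `truth`
#'   (list: `events` data.frame, `layers`, `sigma_ripple_band_uv`, `config`).
#' @export
generate_laminar_lfp <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  nch <- config$n_channels
  L <- config$layers
  epochs <- if (is.null(config$epochs)) default_state_schedule(config$duration_s)
            else validate_epochs(config$epochs)

  g <- onef_gains(n, fs, config$noise$exponent, config$noise$scale_uv)
  sigma_rip <- gain_band_rms(g, fs, 100, 600)

  # shared theta phase with slow frequency drift and amplitude modulation
  th <- config$theta
  f_inst <- th$freq_hz + th$freq_jitter_hz * ar1_noise(n, 0.5, fs)
  phase <- 2 * pi * cumsum(f_inst) / fs
  gain <- state_gain_vector(epochs, n, fs, c("theta", "awake", "REM"),
                            th$lia_gain)
  amod <- 1 + th$amp_mod * pmax(-0.9, pmin(0.9, ar1_noise(n, 1, fs)))
  theta_common <- sin(phase) * gain * amod
  gm <- config$gamma
  gamma_common <- sin(2 * pi * gm$freq_hz * seq_len(n) / fs +
                        stats::runif(1, 0, 2 * pi)) *
    (1 + gm$mod_depth * cos(phase)) / (1 + gm$mod_depth) * gain
  rm(f_inst, amod, gain, phase)

  # large irregular slow activity, shared across channels, gated by LIA
  li <- config$lia
  lia_wave <- numeric(n)
  if (li$delta_amp_uv > 0) {
    k <- 0:(n - 1)
    fabs <- pmin(k, n - k) * fs / n
    gl <- ifelse(fabs >= li$band_hz[1] & fabs <= li$band_hz[2],
                 1 / pmax(fabs, li$band_hz[1])^(config$noise$exponent / 2), 0)
    v <- sum(gl^2) / n^2
    gl <- gl * li$delta_amp_uv / sqrt(v)
    lia_wave <- onef_noise_from_gains(gl) *
      state_gain_vector(epochs, n, fs, "LIA", 0)
    rm(gl, fabs, k)
  }

  ch_idx <- seq_len(nch)
  theta_amp <- th$amp_uv * (0.15 + 0.85 * exp(-(ch_idx - L$slm)^2 /
                                                (2 * th$width_ch^2)))
  phase_side <- ifelse(ch_idx <= floor((L$pyramidale + L$slm) / 2), 1, -1)

  # channel-independent background, consolidated before the sample matrix
  # is allocated so large temporaries never coexist with it
  fixed_common <- gm$amp_uv * gamma_common + lia_wave
  rm(gamma_common, lia_wave)
  big <- n > 5e6
  if (big) gc(FALSE)

  samples <- matrix(0, nrow = nch, ncol = n)
  for (ch in seq(1L, nch, by = 2L)) {
    pair <- onef_noise_pair(g)
    samples[ch, ] <- pair[[1]] +
      (theta_amp[ch] * phase_side[ch]) * theta_common + fixed_common
    if (ch + 1L <= nch) {
      samples[ch + 1L, ] <- pair[[2]] +
        (theta_amp[ch + 1L] * phase_side[ch + 1L]) * theta_common + fixed_common
    }
    rm(pair)
    if (big) gc(FALSE)
  }
  rm(theta_common, fixed_common)
  if (big) gc(FALSE)

  # sharp-wave ripple events during LIA
  rp <- config$ripples
  lia <- epochs[epochs$label == "LIA", , drop = FALSE]
  dur_s <- rp$duration_ms / 1000
  n_ev <- if (!is.null(rp$n_events)) rp$n_events else
    stats::rpois(1, rp$rate_hz * sum(lia$t_end_s - lia$t_start_s))
  t_peaks <- place_event_times(n_ev, lia, rp$min_gap_s, dur_s / 2 + 0.6)
  nwin <- round(dur_s * fs)
  w_rip <- exp(-(ch_idx - L$pyramidale)^2 / (2 * rp$width_ch^2))
  sw <- config$sharp_wave
  w_sw <- exp(-(ch_idx - L$radiatum)^2 / (2 * sw$width_ch^2))
  sw_sigma_n <- sw$sigma_ms / 1000 * fs
  sw_half <- round(4 * sw_sigma_n)
  truth_rows <- vector("list", length(t_peaks))
  for (e in seq_along(t_peaks)) {
    tp <- t_peaks[e]
    z <- stats::runif(1, rp$amp_z[1], rp$amp_z[2])
    A <- amp_for_envelope_z(z, sigma_rip)
    ip <- round(tp * fs) + 1L
    idx <- (ip - nwin %/% 2):(ip - nwin %/% 2 + nwin - 1L)
    burst <- A * tukey_window(nwin, rp$taper) *
      sin(2 * pi * rp$freq_hz * (seq_len(nwin) - 1) / fs +
            stats::runif(1, 0, 2 * pi))
    sw_idx <- (ip - sw_half):(ip + sw_half)
    sw_shape <- -sw$amp_uv * exp(-((sw_idx - ip) / sw_sigma_n)^2 / 2)
    for (ch in which(w_rip > 0.01 | w_sw > 0.01)) {
      if (w_rip[ch] > 0.01)
        samples[ch, idx] <- samples[ch, idx] + w_rip[ch] * burst
      if (w_sw[ch] > 0.01)
        samples[ch, sw_idx] <- samples[ch, sw_idx] + w_sw[ch] * sw_shape
    }
    truth_rows[[e]] <- data.frame(
      type = "ripple", channel = L$pyramidale,
      t_start_s = (idx[1] - 1) / fs, t_peak_s = tp,
      t_end_s = (idx[nwin] - 1) / fs, duration_ms = rp$duration_ms,
      amplitude_uv = A, envelope_z = z, freq_hz = rp$freq_hz,
      sw_amplitude_uv = sw$amp_uv, stringsAsFactors = FALSE)
  }

  # MUA spike trains at the cell-body layers
  mu <- config$mua
  if (mu$rate_hz > 0 && mu$amp_uv > 0) {
    # 3-cycle 1.5 kHz wavelet: spike energy stays above the ripple band
    wlen <- max(8L, round(0.002 * fs))
    tt <- seq_len(wlen) / fs
    spike_wave <- mu$amp_uv * sin(2 * pi * 1500 * tt) *
      0.5 * (1 - cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1)))
    for (layer_ch in c(L$pyramidale, L$granule)) {
      wch <- exp(-(ch_idx - layer_ch)^2 / (2 * mu$width_ch^2))
      n_spk <- stats::rpois(1, mu$rate_hz * config$duration_s)
      at <- sort(ceiling(stats::runif(n_spk, 1, n - wlen)))
      for (s in at) {
        jj <- s:(s + wlen - 1L)
        for (ch in which(wch > 0.05))
          samples[ch, jj] <- samples[ch, jj] + wch[ch] * spike_wave
      }
    }
  }

  labels <- rep(NA_character_, nch)
  labels[seq_len(L$pyramidale - 1)] <- "oriens"
  labels[L$pyramidale] <- "pyramidale"
  if (L$slm - 2 >= L$pyramidale + 1)
    labels[(L$pyramidale + 1):(L$slm - 2)] <- "radiatum"
  labels[max(1, L$slm - 1):min(nch, L$slm + 1)] <- "lacunosum-moleculare"
  if (L$granule - 1 >= L$slm + 2) labels[(L$slm + 2):(L$granule - 1)] <- "moleculare"
  labels[L$granule:min(nch, L$granule + 1)] <- "granule"

  rec <- laminar_recording(samples, fs = fs,
                           probe = probe_geometry(nch, config$spacing_um),
                           layer_labels = labels)
  rec$epochs <- epochs
  truth <- list(events = if (length(truth_rows) > 0) do.call(rbind, truth_rows)
                         else NULL,
                layers = L, sigma_ripple_band_uv = sigma_rip,
                seed = config$seed, config = config)
  list(recording = rec, truth = truth)
}

#' Generate a chronic epidural EEG recording with ground truth
#'
#' SWS epochs carry a slow oscillation plus K-complexes, each followed with
#' probability `kc_prob` by a sleep spindle; REM/awake epochs are
#' theta-dominated. The truth table lists every spindle.
#'
#' @param config A [sim_config()]; relevant fields are `seed`, `duration_s`,
#'   `fs`, `noise`, `epochs` (labels SWS/REM/awake) and the `eeg` section.
#' @return List with `recording` (an [eeg_recording()] with epochs) and
#'   `truth` (list: `events`, `k_complexes`, `sigma_spindle_band_uv`).
#' @export
generate_eeg <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  ee <- config$eeg
  epochs <- if (!is.null(config$epochs)) validate_epochs(config$epochs) else {
    blocks <- list(c("SWS", 200), c("REM", 50), c("awake", 50))
    lab <- character(0); st <- numeric(0); en <- numeric(0); t <- 0
    while (t < config$duration_s - 1e-9) {
      for (b in blocks) {
        if (t >= config$duration_s - 1e-9) break
        lab <- c(lab, b[[1]]); st <- c(st, t)
        t <- min(t + as.numeric(b[[2]]), config$duration_s); en <- c(en, t)
      }
    }
    epoch_table(lab, st, en)
  }

  g <- onef_gains(n, fs, config$noise$exponent, config$noise$scale_uv)
  sigma_sp <- gain_band_rms(g, fs, 7, 16)
  x <- onef_noise_from_gains(g)

  tvec <- (seq_len(n) - 1) / fs
  sws_gain <- state_gain_vector(epochs, n, fs, "SWS", 0)
  rem_gain <- state_gain_vector(epochs, n, fs, c("REM", "awake", "theta"), 0)
  x <- x + ee$slow_amp_uv * sws_gain *
    sin(2 * pi * ee$slow_freq_hz * tvec + stats::runif(1, 0, 2 * pi)) +
    ee$rem_theta_uv * rem_gain *
    sin(2 * pi * ee$rem_theta_hz * tvec + stats::runif(1, 0, 2 * pi))

  sws <- epochs[epochs$label == "SWS", , drop = FALSE]
  dur_s <- ee$spindle_duration_ms / 1000
  t_centers <- place_event_times(ee$n_spindles, sws, ee$spindle_min_gap_s,
                                 dur_s / 2 + 1)
  nwin <- round(dur_s * fs)
  A <- amp_for_envelope_z(ee$spindle_amp_z, sigma_sp)
  kc_sigma_n <- ee$kc_sigma_ms / 1000 * fs
  kc_half <- round(4 * kc_sigma_n)
  truth_rows <- vector("list", length(t_centers))
  kc_times <- numeric(0)
  for (e in seq_along(t_centers)) {
    tp <- t_centers[e]
    ip <- round(tp * fs) + 1L
    idx <- (ip - nwin %/% 2):(ip - nwin %/% 2 + nwin - 1L)
    burst <- A * tukey_window(nwin, ee$spindle_taper) *
      sin(2 * pi * ee$spindle_freq_hz * (seq_len(nwin) - 1) / fs +
            stats::runif(1, 0, 2 * pi))
    x[idx] <- x[idx] + burst
    has_kc <- stats::runif(1) < ee$kc_prob
    if (has_kc) {
      tk <- tp - dur_s / 2 - 0.35
      ik <- round(tk * fs) + 1L
      if (ik - kc_half >= 1) {
        kidx <- (ik - kc_half):(ik + kc_half)
        u <- (kidx - ik) / kc_sigma_n
        x[kidx] <- x[kidx] - ee$kc_amp_uv * u * exp(-u^2 / 2) * exp(0.5)
        kc_times <- c(kc_times, tk)
      }
    }
    truth_rows[[e]] <- data.frame(
      type = "spindle", channel = 1L,
      t_start_s = (idx[1] - 1) / fs, t_peak_s = tp,
      t_end_s = (idx[nwin] - 1) / fs, duration_ms = ee$spindle_duration_ms,
      amplitude_uv = A, envelope_z = ee$spindle_amp_z,
      freq_hz = ee$spindle_freq_hz, stringsAsFactors = FALSE)
  }
  rec <- eeg_recording(x, fs = fs, epochs = epochs)
  truth <- list(events = if (length(truth_rows) > 0) do.call(rbind, truth_rows)
                         else NULL,
                k_complexes = kc_times, sigma_spindle_band_uv = sigma_sp,
                seed = config$seed, config = config)
  list(recording = rec, truth = truth)
}

# continuous alpha-function fEPSP (negative-going), onset at t = 0
alpha_fepsp <- function(t_ms, amp_uv, tau_ms) {
  v <- numeric(length(t_ms))
  pos <- t_ms > 0
  v[pos] <- -amp_uv * (t_ms[pos] / tau_ms) * exp(1 - t_ms[pos] / tau_ms)
  v
}

# least-squares slope (uV/ms) of the 20-80% span of the alpha rising limb,
# evaluated on a dense grid (generator-side truth, estimator-independent)
alpha_ls_slope <- function(amp_uv, tau_ms, dt_ms = 1e-4) {
  tt <- seq(0, tau_ms, by = dt_ms)
  v <- alpha_fepsp(tt, amp_uv, tau_ms)
  i20 <- which(v <= -0.2 * amp_uv)[1]
  i80 <- which(v <= -0.8 * amp_uv)[1]
  span <- i20:i80
  stats::coef(stats::lm(v[span] ~ tt[span]))[[2]]
}

io_sigmoid <- function(I, amp_max, i50, slope) {
  amp_max / (1 + exp(-(I - i50) / slope))
}

#' Generate evoked sweeps with ground truth
#'
#' Single-pulse input/output sweeps over the configured intensity grid plus
#' paired-pulse sweeps (facilitation at 40% of the maximal-response
#' intensity, inhibition at maximal intensity) at the configured intervals.
#' Each sweep = afferent volley (sublinear in intensity) + alpha-function
#' fEPSP (sigmoidal in intensity) + population spike above threshold +
#' white noise at `fepsp_amp_max_uv / snr` RMS.
#'
#' @param config A [sim_config()]; uses `seed` and the `evoked` section.
#' @return List with `io_sweeps` (list of [evoked_sweep()]), `pp_pairs`
#'   (list of paired sweeps with `$interval_ms` and `$mode`), and `truth`.
#' @export
generate_evoked_sweeps <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  ev <- config$evoked
  fs <- ev$fs
  noise_sd <- ev$fepsp_amp_max_uv / ev$snr
  pre_s <- 0.01
  stim_sample <- round(pre_s * fs) + 1L

  make_response <- function(t_ms, I, scale = 1) {
    fe <- scale * io_sigmoid(I, ev$fepsp_amp_max_uv, ev$io_i50_ua, ev$io_slope_ua)
    y <- alpha_fepsp(t_ms - ev$fepsp_latency_ms, fe, ev$fepsp_tau_ms)
    av <- ev$av_amp_max_uv * I / (I + ev$av_i_half_ua)
    avt <- t_ms - ev$av_latency_ms
    in_av <- avt > 0 & avt < 1.5
    y[in_av] <- y[in_av] - av * sin(2 * pi * avt[in_av] / 1.5)
    if (I > ev$ps_threshold_ua) {
      ps <- scale * ev$ps_amp_max_uv * (I - ev$ps_threshold_ua) /
        (max(ev$intensities_ua) - ev$ps_threshold_ua)
      tc <- ev$fepsp_latency_ms + ev$fepsp_tau_ms
      # inverted Ricker: sharp notch with flanking positivities, the
      # classic appearance of a population spike on the field potential
      u <- (t_ms - tc) / ev$ps_sigma_ms
      y <- y - ps * (1 - u^2) * exp(-u^2 / 2)
    }
    y
  }

  sweep_len <- round(0.1 * fs)
  t_ms <- ((seq_len(sweep_len) - stim_sample)) / fs * 1000
  io_sweeps <- list()
  io_truth <- list()
  for (I in ev$intensities_ua) {
    clean <- make_response(t_ms, I)
    for (r in seq_len(ev$n_sweeps)) {
      tr <- clean + stats::rnorm(sweep_len, sd = noise_sd)
      sw <- evoked_sweep(tr, fs, stim_sample, I, site = "radiatum")
      io_sweeps[[length(io_sweeps) + 1]] <- sw
    }
    fe <- io_sigmoid(I, ev$fepsp_amp_max_uv, ev$io_i50_ua, ev$io_slope_ua)
    io_truth[[length(io_truth) + 1]] <- data.frame(
      intensity_ua = I, fepsp_amplitude_uv = fe,
      fepsp_slope_uv_ms = alpha_ls_slope(fe, ev$fepsp_tau_ms, dt_ms = 1e-3),
      av_amplitude_uv = ev$av_amp_max_uv * I / (I + ev$av_i_half_ua),
      ps_present = I > ev$ps_threshold_ua)
  }

  pair_len <- round((pre_s + max(ev$pp_intervals_ms) / 1000 + 0.06) * fs)
  t2_ms <- ((seq_len(pair_len) - stim_sample)) / fs * 1000
  pp_pairs <- list()
  pp_truth <- list()
  for (mode in c("facilitation", "inhibition")) {
    I <- if (mode == "facilitation") ev$pp_fac_intensity_ua else max(ev$intensities_ua)
    factors <- if (mode == "facilitation") ev$pp_facilitation else ev$pp_inhibition
    for (j in seq_along(ev$pp_intervals_ms)) {
      iv <- ev$pp_intervals_ms[j]
      clean <- make_response(t2_ms, I) +
        make_response(t2_ms - iv, I, scale = factors[j])
      for (r in seq_len(ev$n_sweeps)) {
        tr <- clean + stats::rnorm(pair_len, sd = noise_sd)
        sw <- evoked_sweep(tr, fs, stim_sample, I, site = "radiatum")
        sw$interval_ms <- iv
        sw$mode <- mode
        pp_pairs[[length(pp_pairs) + 1]] <- sw
      }
      pp_truth[[length(pp_truth) + 1]] <- data.frame(
        mode = mode, interval_ms = iv, intensity_ua = I, true_ratio = factors[j])
    }
  }

  list(io_sweeps = io_sweeps, pp_pairs = pp_pairs,
       truth = list(io = do.call(rbind, io_truth),
                    pp = do.call(rbind, pp_truth),
                    noise_sd_uv = noise_sd,
                    ps_threshold_ua = ev$ps_threshold_ua,
                    seed = config$seed, config = config))
}

#' Analytic section-area series for stereology fixtures
#'
#' Emits exact cross-section areas of a simple solid at the analyzed section
#' planes (every k-th section of the given thickness), for validating
#' Cavalieri volume estimates against closed-form volumes.
#'
#' @param shape List: `type` in `"sphere"` (field `r_mm`), `"cylinder"`
#'   (`r_mm`, `l_mm`), or `"ellipsoid"` (`a_mm`, `b_mm`, `c_mm`; sections
#'   are taken perpendicular to the `c` axis).
#' @param spacing_um Physical section thickness in micrometres.
#' @param k Every k-th section analyzed.
#' @return A [section_series()]; attribute `volume_mm3` holds the analytic
#'   volume.
#' @export
generate_section_areas <- function(shape, spacing_um, k = 1) {
  d_mm <- spacing_um / 1000 * k
  type <- match.arg(shape$type, c("sphere", "cylinder", "ellipsoid"))
  half <- switch(type,
                 sphere = shape$r_mm,
                 cylinder = shape$l_mm / 2,
                 ellipsoid = shape$c_mm)
  if (half <= 0) stop("nonpositive dimensions")
  z <- seq(-half + d_mm / 2, half, by = d_mm)
  areas <- switch(type,
                  sphere = pmax(0, pi * (shape$r_mm^2 - z^2)),
                  cylinder = rep(pi * shape$r_mm^2, length(z)),
                  ellipsoid = pmax(0, pi * shape$a_mm * shape$b_mm *
                                     (1 - z^2 / shape$c_mm^2)))
  vol <- switch(type,
                sphere = 4 / 3 * pi * shape$r_mm^3,
                cylinder = pi * shape$r_mm^2 * shape$l_mm,
                ellipsoid = 4 / 3 * pi * shape$a_mm * shape$b_mm * shape$c_mm)
  out <- section_series(z, areas, thickness_um = spacing_um, k = k)
  attr(out, "volume_mm3") <- vol
  out
}
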