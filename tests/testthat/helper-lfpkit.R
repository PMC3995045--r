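# shared test helpers: tone construction and tiny quiet scenes

make_tone <- function(freq, fs, dur_s, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(round(dur_s * fs) - 1)) / fs + phase)
}

# simulator config with every structured component silenced: pure 1/f noise
noise_only_config <- function(seed, duration_s, fs, n_channels = 1) {
  sim_config(seed = seed, duration_s = duration_s, fs = fs,
             n_channels = n_channels,
             theta = list(amp_uv = 0), gamma = list(amp_uv = 0),
             ripples = list(rate_hz = 0), mua = list(amp_uv = 0),
             lia = list(delta_amp_uv = 0),
             epochs = epoch_table("LIA", 0, duration_s))
}

# detect ripples restricted to LIA epochs of a laminar scene
detect_lia_ripples <- function(rec, channel, config = ripple_config()) {
  lia <- rec$epochs[rec$epochs$label == "LIA", , drop = FALSE]
  tabs <- lapply(seq_len(nrow(lia)), function(i) {
    seg <- extract_epoch(rec, lia[i, ])
    as.data.frame(detect_band_events(seg$samples[channel, ], seg$fs, config,
                                     channel = channel, t0_s = seg$t0_s))
  })
  event_table(do.call(rbind, tabs))
}
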