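test_that("ripple detector recovers injected bursts with matched features", {
  cfg <- sim_config(seed = 42, duration_s = 60, fs = 20000,
                    ripples = list(n_events = 20),
                    epochs = epoch_table("LIA", 0, 60))
  gen <- generate_laminar_lfp(cfg)
  rec <- gen$recording; truth <- gen$truth
  pyr <- truth$layers$pyramidale
  ev <- detect_band_events(rec$samples[pyr, ], rec$fs, ripple_config(),
                           channel = pyr)
  m <- match_events(ev, truth$events, tol_s = 0.01)
  expect_gte(m$sensitivity, 0.9)
  expect_gte(m$precision, 0.9)
  fe <- characterize_ripples(rec, ev, pyr, truth$layers$radiatum)
  p <- m$pairs
  expect_lte(median(abs(fe$duration_ms[p[, 1]] - 60)), 10)
  expect_lte(median(abs(fe$peak_freq_hz[p[, 1]] - 150)), 10)
  expect_lte(median(abs(fe$sw_amplitude_uv[p[, 1]] - 300) / 300), 0.10)
  expect_equal(attr(fe, "rate_hz"), nrow(ev) / 60)

  # threshold monotonicity: raising detect_z cannot add events, and an
  # absurd threshold detects nothing
  ev_hi <- detect_band_events(rec$samples[pyr, ], rec$fs,
                              ripple_config(detect_z = 10, duration_z = 1.6),
                              channel = pyr)
  expect_lte(nrow(ev_hi), nrow(ev))
  ev_vhi <- detect_band_events(rec$samples[pyr, ], rec$fs,
                               ripple_config(detect_z = 40, duration_z = 1.6),
                               channel = pyr)
  expect_equal(nrow(ev_vhi), 0)
})

test_that("detector enforces duration, merge-gap and degenerate-input rules", {
  cfg <- ripple_config()
  expect_error(detect_band_events(numeric(20000), 20000, cfg), "degenerate signal")
  expect_error(detect_band_events(rnorm(500), 20000, cfg), "epoch too short")
  gen <- generate_laminar_lfp(sim_config(seed = 43, duration_s = 30, fs = 20000,
                                         n_channels = 2,
                                         ripples = list(n_events = 12,
                                                        min_gap_s = 0.3),
                                         epochs = epoch_table("LIA", 0, 30)))
  ev <- detect_band_events(gen$recording$samples[1, ], 20000,
                           ripple_config(), channel = 1)
  expect_true(all(ev$duration_ms >= ripple_config()$min_duration_ms))
  if (nrow(ev) > 1) {
    gaps <- ev$t_start_s[-1] - ev$t_end_s[-nrow(ev)]
    expect_true(all(gaps * 1000 >= ripple_config()$merge_gap_ms - 1e-9))
  }
  expect_true(all(ev$t_start_s <= ev$t_peak_s & ev$t_peak_s <= ev$t_end_s))
})

test_that("events near the recording edge are flagged and still measured", {
  set.seed(44)
  fs <- 20000
  x <- rnorm(fs)  # 1 s
  rec <- laminar_recording(rbind(x, rnorm(fs)), fs, probe_geometry(2, 25))
  ev <- event_table(data.frame(type = "ripple", channel = 1,
                               t_start_s = 0.03, t_peak_s = 0.05,
                               t_end_s = 0.08, duration_ms = 50, peak_z = 5))
  fe <- characterize_ripples(rec, ev, 1, 2)
  expect_true(fe$edge[1])
  expect_true(is.finite(fe$power_db[1]))
})

test_that("spindle features follow the stated conventions", {
  cfg <- sim_config(seed = 45, duration_s = 120, fs = 2000,
                    eeg = list(n_spindles = 10),
                    epochs = epoch_table("SWS", 0, 120))
  gen <- generate_eeg(cfg)
  ev <- detect_band_events(gen$recording$trace, 2000, spindle_config(),
                           channel = 1)
  m <- match_events(ev, gen$truth$events, tol_s = 0.1)
  expect_gte(m$sensitivity, 0.9)
  fe <- characterize_spindles(gen$recording, ev)
  expect_true(all(is.finite(fe$power_db)))
  # inter-spindle interval arithmetic: t_start(k+1) - t_end(k)
  if (nrow(ev) > 1) {
    expect_equal(fe$isi_s[1], ev$t_start_s[2] - ev$t_end_s[1])
    expect_true(is.na(fe$isi_s[nrow(fe)]))
  }
  # a lone spindle has no interval
  one <- ev[1, , drop = FALSE]
  fe1 <- characterize_spindles(gen$recording, one)
  expect_true(is.na(fe1$isi_s))
})

test_that("spindle power is computed in 10-16 Hz even though detection runs 7-16", {
  expect_equal(spindle_config()$band$band_lo_hz, 7)
  expect_equal(spindle_config()$band$band_hi_hz, 16)
  expect_equal(formals(characterize_spindles)$power_band, quote(c(10, 16)))
})

test_that("interval matching is one-to-one and scores sensibly", {
  truth <- data.frame(t_start_s = c(1, 5), t_peak_s = c(1.03, 5.03),
                      t_end_s = c(1.06, 5.06))
  det <- data.frame(t_start_s = c(1.0, 1.01, 9), t_peak_s = c(1.02, 1.04, 9.02),
                    t_end_s = c(1.05, 1.07, 9.05))
  m <- match_events(det, truth, tol_s = 0.01)
  expect_equal(m$n_matched, 1L)  # two detections cannot claim one event
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$precision, 1 / 3)
  m0 <- match_events(det[0, ], truth, tol_s = 0.01)
  expect_equal(m0$sensitivity, 0)
})
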