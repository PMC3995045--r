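test_that("identical config and seed give bit-identical outputs", {
  cfg <- sim_config(seed = 81, duration_s = 4, fs = 2000, n_channels = 4)
  a <- generate_laminar_lfp(cfg)
  b <- generate_laminar_lfp(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$events, b$truth$events)
  e1 <- generate_eeg(sim_config(seed = 82, duration_s = 30, fs = 2000,
                                eeg = list(n_spindles = 3)))
  e2 <- generate_eeg(sim_config(seed = 82, duration_s = 30, fs = 2000,
                                eeg = list(n_spindles = 3)))
  expect_identical(e1$recording$trace, e2$recording$trace)
  v1 <- generate_evoked_sweeps(sim_config(seed = 83, evoked = list(n_sweeps = 2)))
  v2 <- generate_evoked_sweeps(sim_config(seed = 83, evoked = list(n_sweeps = 2)))
  expect_identical(v1$io_sweeps[[5]]$trace, v2$io_sweeps[[5]]$trace)
  # different seeds differ
  c2 <- generate_laminar_lfp(sim_config(seed = 99, duration_s = 4, fs = 2000,
                                        n_channels = 4))
  expect_false(identical(a$recording$samples, c2$recording$samples))
})

test_that("Poisson event counts fall in the central 99% interval", {
  cfg <- sim_config(seed = 84, duration_s = 600, fs = 1000, n_channels = 2,
                    ripples = list(rate_hz = 0.2), mua = list(amp_uv = 0),
                    epochs = epoch_table("LIA", 0, 600))
  gen <- generate_laminar_lfp(cfg)
  n <- nrow(gen$truth$events)
  expect_gte(n, qpois(0.005, 0.2 * 600))
  expect_lte(n, qpois(0.995, 0.2 * 600))
  # fixed-count override and min-gap invariant
  cfg2 <- sim_config(seed = 85, duration_s = 60, fs = 1000, n_channels = 2,
                     ripples = list(n_events = 15), mua = list(amp_uv = 0),
                     epochs = epoch_table("LIA", 0, 60))
  tr <- generate_laminar_lfp(cfg2)$truth$events
  expect_equal(nrow(tr), 15)
  expect_true(all(diff(tr$t_peak_s) >= 0.5 - 1e-9))
})

test_that("generated theta shows the injected pyr-slm phase reversal", {
  cfg <- sim_config(seed = 86, duration_s = 20, fs = 2000, n_channels = 8,
                    mua = list(amp_uv = 0), ripples = list(rate_hz = 0),
                    epochs = epoch_table("theta", 0, 20))
  gen <- generate_laminar_lfp(cfg)
  L <- gen$truth$layers
  ph <- phase_lag_deg(gen$recording$samples[L$pyramidale, ],
                      gen$recording$samples[L$slm, ], 2000)
  expect_lt(abs(abs(ph) - 180), 20)
  # theta amplitude peaks at slm
  amps <- apply(gen$recording$samples, 1, function(x)
    band_power(average_spectrum(x, 2000, 1, 1), 4, 10)$area_db)
  expect_lte(abs(which.max(amps) - L$slm), 1)
})

test_that("EEG truth matches construction and SWS carries the sigma band", {
  cfg <- sim_config(seed = 87, duration_s = 600, fs = 2000)
  gen <- generate_eeg(cfg)
  tr <- gen$truth$events
  expect_equal(nrow(tr), 60)
  expect_equal(unique(tr$duration_ms), 800)
  ep <- gen$recording$epochs
  sws_idx <- lfpkit:::epoch_index(ep[ep$label == "SWS", , drop = FALSE],
                                  tr$t_peak_s)
  expect_true(all(!is.na(sws_idx)))  # spindles only inside SWS
  # K-complex coupling close to the configured probability
  expect_gt(length(gen$truth$k_complexes) / 60, 0.45)
  expect_lt(length(gen$truth$k_complexes) / 60, 0.9)
  # 10-16 Hz linear area larger in SWS than REM
  area <- function(label) {
    rows <- ep[ep$label == label, , drop = FALSE]
    xs <- unlist(lapply(seq_len(nrow(rows)), function(i)
      extract_epoch(gen$recording, rows[i, ])$trace))
    band_power(average_spectrum(xs, 2000, segment_s = 5, resolution_hz = 1),
               10, 16)$area_linear
  }
  expect_gt(area("SWS"), area("REM"))
})

test_that("evoked truth respects the threshold and paired-pulse construction", {
  gen <- generate_evoked_sweeps(sim_config(seed = 88, evoked = list(n_sweeps = 2)))
  expect_equal(length(unique(vapply(gen$io_sweeps,
                                    function(s) s$intensity_ua, numeric(1)))), 8)
  io <- gen$truth$io
  expect_true(all(!io$ps_present[io$intensity_ua <= 400]))
  expect_true(all(io$ps_present[io$intensity_ua > 400]))
  expect_equal(gen$truth$pp$true_ratio[gen$truth$pp$mode == "facilitation" &
                                         gen$truth$pp$interval_ms == 50], 1.4)
})

test_that("section-area fixtures are analytic and converge", {
  s <- generate_section_areas(list(type = "sphere", r_mm = 1), 50, 1)
  iz <- which.min(abs(s$positions_mm))
  expect_equal(s$areas_mm2[iz], pi * (1 - s$positions_mm[iz]^2), tolerance = 1e-12)
  cy <- generate_section_areas(list(type = "cylinder", r_mm = 0.5, l_mm = 2), 100, 1)
  expect_true(all(cy$areas_mm2 == pi * 0.25))
  expect_equal(cavalieri_volume(cy), attr(cy, "volume_mm3"), tolerance = 0.05)
  el <- generate_section_areas(list(type = "ellipsoid", a_mm = 1, b_mm = 0.5,
                                    c_mm = 2), 20, 1)
  expect_equal(cavalieri_volume(el), attr(el, "volume_mm3"), tolerance = 0.01)
  expect_error(generate_section_areas(list(type = "sphere", r_mm = -1), 50),
               "nonpositive")
})

test_that("unknown config keys are rejected", {
  expect_error(sim_config(ripples = list(rate = 1)), "unknown config key")
  expect_error(sim_config(noise = list(color = "pink")), "unknown config key")
})
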