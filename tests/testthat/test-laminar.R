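test_that("CSD is zero on depth-affine potentials and exact on quadratics", {
  pr <- probe_geometry(10, 25)
  z <- probe_depths(pr)
  Vlin <- matrix(rep(7 + 0.4 * z, 5), nrow = 10)
  cs <- compute_csd(laminar_recording(Vlin, 1000, pr))
  expect_lt(max(abs(cs$csd)), 1e-12 * max(abs(Vlin)))
  c2 <- 3e-3
  Vq <- matrix(rep(c2 * z^2, 5), nrow = 10)
  csq <- compute_csd(laminar_recording(Vq, 1000, pr))
  expect_equal(unname(csq$csd[, 1]), rep(-2 * c2, 8), tolerance = 1e-9)
  expect_error(compute_csd(laminar_recording(matrix(0, 2, 5), 1000,
                                             probe_geometry(2, 25))),
               "insufficient channels")
})

test_that("CSD matches the analytic second derivative of a Gaussian profile", {
  pr <- probe_geometry(32, 25)
  z <- probe_depths(pr)
  z0 <- z[16]; sig <- 7 * 25  # sigma of 7 contacts, in um
  # negative Gaussian LFP trough: a sink at its centre, sources flanking
  prof <- -100 * exp(-(z - z0)^2 / (2 * sig^2))
  cs <- compute_csd(laminar_recording(matrix(rep(prof, 3), nrow = 32), 1000, pr))
  analytic <- 100 * exp(-(z - z0)^2 / (2 * sig^2)) * ((z - z0)^2 - sig^2) / sig^4
  got <- cs$csd[, 1]
  want <- analytic[2:31]
  # compare where the analytic curvature is substantial: the sink at the
  # peak and the flanking sources
  strong <- abs(want) > 0.2 * max(abs(want))
  expect_lt(max(abs(got[strong] - want[strong]) / abs(want[strong])), 0.02)
  # sink (negative CSD) at the trough, sources on both flanks
  expect_lt(got[15], 0)
  expect_gt(max(got[1:10]), 0)
  expect_gt(max(got[20:30]), 0)
})

test_that("CSD is linear in the input potentials", {
  pr <- probe_geometry(6, 25)
  set.seed(21)
  A <- matrix(rnorm(60), 6); B <- matrix(rnorm(60), 6)
  ca <- compute_csd(laminar_recording(A, 1000, pr))$csd
  cb <- compute_csd(laminar_recording(B, 1000, pr))$csd
  cab <- compute_csd(laminar_recording(2 * A - 5 * B, 1000, pr))$csd
  expect_equal(cab, 2 * ca - 5 * cb, tolerance = 1e-12)
})

test_that("MUA profile peaks at spiking layers and stays flat on noise", {
  cfg <- sim_config(seed = 31, duration_s = 8, fs = 20000, n_channels = 16,
                    theta = list(amp_uv = 0), gamma = list(amp_uv = 0),
                    ripples = list(rate_hz = 0), lia = list(delta_amp_uv = 0),
                    layers = list(pyramidale = 4, radiatum = 6, slm = 8,
                                  granule = 12),
                    epochs = epoch_table("LIA", 0, 8))
  gen <- generate_laminar_lfp(cfg)
  mp <- mua_power_profile(gen$recording)
  # double cell layer: the top channels sit at both injected layers
  ord <- order(mp$power_db, decreasing = TRUE)
  expect_true(any(abs(ord[1:3] - 4) <= 1))
  expect_true(any(abs(ord[1:3] - 12) <= 1))

  noise <- generate_laminar_lfp(noise_only_config(32, 8, 20000, n_channels = 8))
  mpn <- mua_power_profile(noise$recording)
  expect_lt(diff(range(mpn$power_db)), 3)
  expect_error(mua_power_profile(gen$recording, band = c(500, 15000)),
               "exceeds Nyquist")
})

test_that("layer identification recovers pyr/rad/slm/granule on a scene", {
  cfg <- sim_config(seed = 33, duration_s = 12, fs = 20000,
                    ripples = list(rate_hz = 1))
  gen <- generate_laminar_lfp(cfg)
  ev <- detect_lia_ripples(gen$recording, gen$truth$layers$pyramidale)
  lm_ <- identify_layers(gen$recording, ev)
  got <- setNames(lm_$channel, lm_$layer)
  expect_lte(abs(got[["pyramidale"]] - gen$truth$layers$pyramidale), 1)
  expect_lte(abs(got[["radiatum"]] - gen$truth$layers$radiatum), 1)
  expect_lte(abs(got[["lacunosum-moleculare"]] - gen$truth$layers$slm), 1)
  # anatomical ordering on every successful assignment
  ch <- got[c("pyramidale", "radiatum", "lacunosum-moleculare")]
  expect_true(all(diff(ch) > 0))
})

test_that("without ripples pyramidale is unresolved but slm is still found", {
  cfg <- sim_config(seed = 34, duration_s = 10, fs = 20000,
                    ripples = list(rate_hz = 0))
  gen <- generate_laminar_lfp(cfg)
  lm_ <- identify_layers(gen$recording, lfpkit:::empty_event_table("ripple"))
  expect_equal(lm_$evidence[lm_$layer == "pyramidale"], "unresolved:no-ripples")
  expect_true(is.na(lm_$channel[lm_$layer == "pyramidale"]))
  slm_row <- lm_[lm_$layer == "lacunosum-moleculare", ]
  expect_false(is.na(slm_row$channel))
  expect_lte(abs(slm_row$channel - gen$truth$layers$slm), 1)
  expect_equal(slm_row$evidence, "theta-power-only")
})

test_that("theta phase reverses by ~180 degrees between pyr and slm", {
  cfg <- sim_config(seed = 35, duration_s = 20, fs = 2000, n_channels = 8,
                    mua = list(amp_uv = 0), ripples = list(rate_hz = 0),
                    epochs = epoch_table("theta", 0, 20))
  gen <- generate_laminar_lfp(cfg)
  L <- gen$truth$layers
  ph <- phase_lag_deg(gen$recording$samples[L$pyramidale, ],
                      gen$recording$samples[L$slm, ], 2000)
  expect_lt(abs(abs(ph) - 180), 20)
})
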