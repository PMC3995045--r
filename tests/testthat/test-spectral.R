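test_that("averaged spectra locate tones and average linearly", {
  fs <- 1000
  sp <- average_spectrum(make_tone(6, fs, 10), fs, 1, 1)
  expect_equal(sp$freqs_hz[which.max(sp$power_db)], 6)
  expect_equal(peak_frequency(sp, c(1, 20)), 6)
  # a unit tone integrates to 0.5 uV^2
  expect_equal(band_power(sp, 4, 8)$area_linear, 0.5, tolerance = 0.02)

  # averaging two segments equals the mean of their individual linear spectra
  set.seed(7)
  x <- rnorm(2000)
  both <- average_spectrum(x, fs, 1, 1)
  s1 <- average_spectrum(x[1:1000], fs, 1, 1)
  s2 <- average_spectrum(x[1001:2000], fs, 1, 1)
  expect_equal(10^(both$power_db / 10),
               (10^(s1$power_db / 10) + 10^(s2$power_db / 10)) / 2,
               tolerance = 1e-9)
  expect_error(average_spectrum(rnorm(500), fs, 1, 1), "insufficient data")
})

test_that("white-noise PSD matches the analytic one-sided level 2/fs", {
  fs <- 1000
  set.seed(11)
  sp <- average_spectrum(rnorm(100 * fs), fs, 1, 1)
  lin <- 10^(sp$power_db / 10)
  level <- 2 / fs
  se <- level / sqrt(100)
  inner <- sp$freqs_hz > 0 & sp$freqs_hz < fs / 2
  expect_equal(mean(lin[inner]), level, tolerance = 0.01)
  expect_gt(mean(abs(lin[inner] - level) <= 3 * se), 0.98)
})

test_that("band power follows the closed-interval area rule", {
  sp <- lfpkit:::new_power_spectrum(0:500, rep(0, 501), 1, 1)  # 1 uV^2/Hz flat
  bp <- band_power(sp, 4, 10)
  expect_equal(bp$area_linear, 7)              # 7 bins x 1 Hz
  expect_equal(bp$area_db, 10 * log10(7), tolerance = 1e-12)
  expect_equal(band_power(sp, 5, 5)$area_linear, 1)  # single bin
  expect_error(band_power(sp, 5.2, 5.4), "no bins in band")

  # Parseval: total linear area matches time-domain variance within 5%
  fs <- 1000
  set.seed(12)
  x <- rnorm(20 * fs)
  tot <- band_power(average_spectrum(x, fs, 1, 1), 0, fs / 2)
  expect_equal(tot$area_linear, var(x), tolerance = 0.05)
})

test_that("1/f normalization zeroes the reference band and is gain invariant", {
  fs <- 2500
  set.seed(13)
  x <- rnorm(30 * fs)
  sp <- normalize_1f(average_spectrum(x, fs, 1, 1))
  sel <- sp$freqs_hz >= 500 & sp$freqs_hz <= 1000
  expect_lt(abs(10 * log10(mean(10^(sp$power_db[sel] / 10)))), 1e-9)
  b1 <- band_power(sp, 4, 10)$area_db
  spg <- normalize_1f(average_spectrum(17.3 * x, fs, 1, 1))
  expect_lt(abs(band_power(spg, 4, 10)$area_db - b1), 1e-6)
  expect_error(normalize_1f(average_spectrum(rnorm(5000), 1000, 1, 1)),
               "reference band unavailable")

  # synthetic PSD proportional to 1/f: normalized theta area equals the
  # independently computed ratio of band sums
  freqs <- 0:1000
  lin <- c(0, 1 / freqs[-1])
  spf <- lfpkit:::new_power_spectrum(freqs, 10 * log10(pmax(lin, 1e-300)), 1, 1)
  nf <- normalize_1f(spf)
  expected <- sum(1 / (4:10)) / mean(1 / (500:1000))
  expect_equal(band_power(nf, 4, 10)$area_linear, expected, tolerance = 1e-9)
})

test_that("peak frequency uses dB maxima with lowest-frequency tie-break", {
  fs <- 1000
  sp <- average_spectrum(make_tone(5.5, fs, 8), fs, segment_s = 2,
                         resolution_hz = 0.5)
  expect_equal(peak_frequency(sp, c(4, 10)), 5.5)
  # off-grid tone lands on the nearest bin
  sp2 <- average_spectrum(make_tone(5.3, fs, 8), fs, segment_s = 2,
                          resolution_hz = 0.5)
  expect_equal(peak_frequency(sp2, c(4, 10)), 5.5)
  # exact tie broken to the lowest frequency
  spt <- lfpkit:::new_power_spectrum(0:20, c(rep(-10, 5), 3, -10, 3, rep(-10, 13)), 1, 1)
  expect_equal(peak_frequency(spt, c(0, 20)), 5)
  expect_error(peak_frequency(spt, c(30, 40)), "no bins in band")
})

test_that("theta segment selection responds to band content", {
  fs <- 1000
  expect_length(select_theta_segments(make_tone(6, fs, 10), fs), 10)
  expect_length(select_theta_segments(make_tone(2, fs, 10), fs), 0)
})

test_that("multitaper map has the stated hop and tracks tone and chirp ridges", {
  fs <- 20000
  tf <- multitaper_tfr(make_tone(150, fs, 2), fs)
  expect_equal(tf$hop_s, 0.4 * (1 - 0.977))
  expect_equal(tf$hop_s * 1000, 9.2, tolerance = 1e-9)
  ridge_db <- tf$power_db[tf$freqs_hz == 150, ]
  inner <- 5:(length(ridge_db) - 5)
  expect_lt(diff(range(ridge_db[inner])), 1)
  expect_true(all(apply(tf$power_db[, inner], 2, which.max) ==
                    which(tf$freqs_hz == 150)))

  # linear chirp 100 -> 250 Hz: ridge frequency increases with time
  fs2 <- 2000; dur <- 4
  t <- (0:(fs2 * dur - 1)) / fs2
  chirp <- sin(2 * pi * (100 * t + (150 / dur) / 2 * t^2))
  tf2 <- multitaper_tfr(chirp, fs2, window_s = 0.4, overlap = 0.5,
                        resolution_hz = 10)
  ridge <- tf2$freqs_hz[apply(tf2$power_db, 2, which.max)]
  expect_true(all(diff(ridge) >= 0))
  expect_gt(ridge[length(ridge)] - ridge[1], 100)
  expect_error(multitaper_tfr(rnorm(100), fs), "insufficient data")
})

test_that("DPSS tapers are unit-norm and orthogonal", {
  v <- lfpkit:::dpss_exact(256, 3, 5)
  G <- t(v) %*% v
  expect_equal(G, diag(5), tolerance = 1e-8)
  # interpolated long tapers keep unit norm and near-orthogonality
  w <- dpss_tapers(4096, 3, 5)
  expect_equal(colSums(w^2), rep(1, 5), tolerance = 1e-9)
  expect_lt(max(abs((t(w) %*% w)[upper.tri(diag(5))])), 0.01)
})
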