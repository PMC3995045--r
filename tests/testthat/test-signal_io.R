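test_that("int16 recordings are scaled to microvolts on read", {
  td <- withr::local_tempdir()
  dp <- file.path(td, "r.dat"); mp <- file.path(td, "r.json")
  con <- file(dp, "wb")
  writeBin(as.integer(c(2, 4, 6, 8, 10, -2, -4, -6, -8, -10)), con,
           size = 2L, endian = "little")
  close(con)
  jsonlite::write_json(list(fs = 1000, n_channels = 2, dtype = "int16",
                            scale_uv_per_bit = 0.5, spacing_um = 25),
                       mp, auto_unbox = TRUE)
  rec <- read_recording(dp, mp)
  expect_equal(dim(rec$samples), c(2, 5))
  expect_equal(rec$samples[, 1], c(1, 2))   # 2 * 0.5, 4 * 0.5
  expect_equal(rec$samples[2, 5], -5)
})

test_that("write/read round-trips are exact (float32) and bit-bounded (int16)", {
  td <- withr::local_tempdir()
  set.seed(1)
  rec <- laminar_recording(matrix(rnorm(40, sd = 50), nrow = 4), fs = 2000,
                           probe = probe_geometry(4, 25))
  dp <- file.path(td, "a.dat"); mp <- file.path(td, "a.json")
  write_recording(rec, dp, mp, dtype = "float32")
  back <- read_recording(dp, mp)
  storage.mode(rec$samples) <- "double"
  expect_equal(back$samples, matrix(as.numeric(writeBin(as.numeric(rec$samples),
    raw(), size = 4) |> readBin(numeric(), n = 40, size = 4)), nrow = 4))
  expect_equal(back$fs, 2000)
  expect_equal(back$probe$spacing_um, 25)

  write_recording(rec, dp, mp, dtype = "int16", scale_uv_per_bit = 0.195)
  back2 <- read_recording(dp, mp)
  expect_lte(max(abs(back2$samples - rec$samples)), 0.195 / 2 + 1e-12)
  # int16 mode round-trips its own quantized values bit-exactly
  write_recording(back2, dp, mp, dtype = "int16", scale_uv_per_bit = 0.195)
  expect_identical(read_recording(dp, mp)$samples, back2$samples)
})

test_that("malformed files and metadata are rejected with clear errors", {
  td <- withr::local_tempdir()
  dp <- file.path(td, "t.dat"); mp <- file.path(td, "t.json")
  con <- file(dp, "wb")
  writeBin(as.integer(1:10), con, size = 2L, endian = "little")
  close(con)
  jsonlite::write_json(list(fs = 1000, n_channels = 3, dtype = "int16",
                            scale_uv_per_bit = 1), mp, auto_unbox = TRUE)
  expect_error(read_recording(dp, mp), "truncated file")
  jsonlite::write_json(list(fs = 1000, dtype = "int16"), mp, auto_unbox = TRUE)
  expect_error(read_recording(dp, mp), "invalid metadata")
  rec <- eeg_recording(rnorm(10), fs = 100)
  rec$trace[3] <- NA
  expect_error(write_recording(rec, dp, mp), "non-finite")
  suppressWarnings(
    expect_error(write_recording(eeg_recording(rnorm(10), 100),
                                 file.path(td, "no/such/dir/x.dat"), mp),
                 "cannot write"))
})

test_that("extract_epoch slices half-open intervals with exact sample counts", {
  eeg <- eeg_recording(rnorm(6000), fs = 2000)
  seg <- extract_epoch(eeg, list(t_start_s = 0, t_end_s = 1))
  expect_length(seg$trace, 2000)
  expect_error(extract_epoch(eeg, list(t_start_s = 1, t_end_s = 1)),
               "epoch out of range")
  expect_error(extract_epoch(eeg, list(t_start_s = 2, t_end_s = 4)),
               "epoch out of range")
  # adjacent epochs partition the parent slice
  a <- extract_epoch(eeg, list(t_start_s = 0.5, t_end_s = 1.0))
  b <- extract_epoch(eeg, list(t_start_s = 1.0, t_end_s = 1.5))
  parent <- extract_epoch(eeg, list(t_start_s = 0.5, t_end_s = 1.5))
  expect_equal(c(a$trace, b$trace), parent$trace)
  expect_equal(a$t0_s, 0.5)
})

test_that("event tables round-trip through CSV and enforce invariants", {
  td <- withr::local_tempdir()
  p <- file.path(td, "ev.csv")
  empty <- lfpkit:::empty_event_table("ripple")
  write_event_table(empty, p)
  expect_equal(nrow(read_event_table(p)), 0)

  df <- data.frame(type = "ripple", channel = 5L,
                   t_start_s = c(1.0, 2.0, 0.5), t_peak_s = c(1.01, 2.02, 0.52),
                   t_end_s = c(1.05, 2.06, 0.55),
                   duration_ms = c(50, 60, 50), peak_z = c(3, 4, 5))
  tab <- event_table(df)
  expect_equal(tab$t_peak_s, c(0.52, 1.01, 2.02))  # sorted by peak
  write_event_table(tab, p)
  back <- read_event_table(p)
  expect_equal(back$duration_ms, tab$duration_ms, tolerance = 1e-6)
  expect_equal(back$t_peak_s, tab$t_peak_s, tolerance = 1e-6)

  bad <- df; bad$t_start_s[2] <- 0.51; bad$t_peak_s[2] <- 0.53; bad$t_end_s[2] <- 0.6
  expect_error(event_table(bad), "overlapping")
  utils::write.csv(data.frame(x = 1), p, row.names = FALSE)
  expect_error(read_event_table(p), "invalid event table")
})

test_that("epoch tables validate labels, ordering and round-trip", {
  td <- withr::local_tempdir()
  ep <- epoch_table(c("SWS", "REM"), c(0, 100), c(100, 150))
  p <- file.path(td, "ep.csv")
  write_epochs(ep, p)
  expect_equal(as.data.frame(read_epochs(p)), as.data.frame(ep))
  expect_error(epoch_table("nap", 0, 10), "invalid epoch label")
  expect_error(epoch_table(c("SWS", "SWS"), c(0, 5), c(10, 15)),
               "non-overlapping")
})
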