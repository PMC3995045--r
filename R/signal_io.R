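#' Probe geometry of a laminar multi-site electrode
#'
#' Describes a linear silicon probe with uniformly spaced contacts.
#' Channel indices are 1-based and increase with depth (dorsal to ventral).
#'
#' @param n_channels Number of contacts (>= 1).
#' @param spacing_um Vertical contact spacing in micrometres (> 0).
#' @param depth0_um Depth of channel 1 in micrometres (default 0).
#' @return An object of class `probe_geometry`.
#' @examples
#' probe_geometry(32, 25)
#' @export
probe_geometry <- function(n_channels, spacing_um, depth0_um = 0) {
  n_channels <- as.integer(n_channels)
  if (length(n_channels) != 1L || is.na(n_channels) || n_channels < 1L)
    stop("n_channels must be a single integer >= 1")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stop("spacing_um must be a single positive number")
  structure(list(n_channels = n_channels,
                 spacing_um = as.numeric(spacing_um),
                 depth0_um = as.numeric(depth0_um)),
            class = "probe_geometry")
}

#' Channel depths of a probe
#'
#' @param probe A [probe_geometry()].
#' @return Numeric vector of contact depths in micrometres.
#' @export
probe_depths <- function(probe) {
  probe$depth0_um + (seq_len(probe$n_channels) - 1) * probe$spacing_um
}

#' Laminar multi-channel recording
#'
#' Container for an extracellular recording from a linear probe. Samples are
#' stored channels x samples in microvolts.
#'
#' @param samples Numeric matrix `[n_channels x n_samples]`, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param probe A [probe_geometry()] whose `n_channels` matches `nrow(samples)`.
#' @param layer_labels Optional character vector of stratum labels, one per
#'   channel (e.g. `"pyramidale"`, `"radiatum"`).
#' @param t0_s Time of the first sample in seconds (default 0); carries epoch
#'   offsets through [extract_epoch()].
#' @return An object of class `laminar_recording`.
#' @export
laminar_recording <- function(samples, fs, probe, layer_labels = NULL, t0_s = 0) {
  if (!is.matrix(samples)) stop("samples must be a matrix [channels x samples]")
  if (!finite_matrix(samples)) stop("invalid samples: non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (!inherits(probe, "probe_geometry")) stop("probe must be a probe_geometry")
  if (nrow(samples) != probe$n_channels)
    stop("invalid metadata: row count does not match probe n_channels")
  if (!is.null(layer_labels) && length(layer_labels) != nrow(samples))
    stop("layer_labels must have one entry per channel")
  structure(list(samples = samples, fs = as.numeric(fs), probe = probe,
                 layer_labels = layer_labels, t0_s = as.numeric(t0_s)),
            class = "laminar_recording")
}

#' Single-channel EEG recording
#'
#' @param trace Numeric vector in microvolts.
#' @param fs Sampling rate in Hz.
#' @param epochs Optional epoch table, see [epoch_table()].
#' @param t0_s Time of first sample in seconds.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(trace, fs, epochs = NULL, t0_s = 0) {
  if (!is.numeric(trace) || !all(is.finite(trace))) stop("invalid samples: non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  dur <- length(trace) / fs
  if (!is.null(epochs)) {
    epochs <- validate_epochs(epochs)
    if (any(epochs$t_end_s > t0_s + dur + 1e-9))
      stop("epoch out of range: epochs must lie within the trace duration")
  }
  structure(list(trace = as.numeric(trace), fs = as.numeric(fs),
                 epochs = epochs, t0_s = as.numeric(t0_s)),
            class = "eeg_recording")
}

# allocation-free finiteness check: the min/max primitives reduce in place
# and surface NA/NaN/Inf, so no gigabyte-scale copy or logical mask is ever
# materialized for long multi-channel recordings (range() would copy via c())
finite_matrix <- function(m) {
  lo <- min(m)
  is.finite(lo) && is.finite(max(m))
}

EPOCH_LABELS <- c("theta", "LIA", "awake", "REM", "SWS")

#' Build a labelled epoch table
#'
#' Epochs are half-open intervals `[t_start_s, t_end_s)` so that adjacent
#' epochs partition time. Labels follow the behavioural-state vocabulary
#' `theta`, `LIA`, `awake`, `REM`, `SWS`.
#'
#' @param label Character vector of state labels.
#' @param t_start_s,t_end_s Numeric vectors of start/end times in seconds.
#' @return A `data.frame` with class `epoch_table`.
#' @export
epoch_table <- function(label, t_start_s, t_end_s) {
  df <- data.frame(label = as.character(label),
                   t_start_s = as.numeric(t_start_s),
                   t_end_s = as.numeric(t_end_s),
                   stringsAsFactors = FALSE)
  validate_epochs(df)
}

validate_epochs <- function(df) {
  stopifnot(all(c("label", "t_start_s", "t_end_s") %in% names(df)))
  if (!all(df$label %in% EPOCH_LABELS))
    stop("invalid epoch label; must be one of: ", paste(EPOCH_LABELS, collapse = ", "))
  if (any(df$t_end_s <= df$t_start_s)) stop("epoch out of range: t_end_s must exceed t_start_s")
  df <- df[order(df$t_start_s), , drop = FALSE]
  if (nrow(df) > 1 && any(df$t_start_s[-1] < df$t_end_s[-nrow(df)] - 1e-9))
    stop("epochs must be non-overlapping")
  rownames(df) <- NULL
  class(df) <- c("epoch_table", "data.frame")
  df
}

#' Read a raw binary recording with its JSON sidecar
#'
#' The data file holds interleaved sample-major values (channel 1..n for
#' sample 1, then sample 2, ...), either little-endian `int16` scaled by
#' `scale_uv_per_bit` or `float32` already in microvolts. The sidecar is a
#' JSON object with at least `fs`, `n_channels`, `dtype` and, for int16,
#' `scale_uv_per_bit`; optional keys `spacing_um`, `depth0_um`,
#' `layer_labels`, `kind` (`"laminar"` or `"eeg"`), `t0_s`.
#'
#' @param path_data Path to the binary data file.
#' @param path_meta Path to the JSON sidecar.
#' @return A [laminar_recording()] (or [eeg_recording()] when the sidecar
#'   declares `kind: eeg` with one channel), samples in microvolts.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path_data, path_meta) {
  if (!file.exists(path_meta)) stop("invalid metadata: sidecar not found: ", path_meta)
  meta <- jsonlite::read_json(path_meta, simplifyVector = TRUE)
  for (key in c("fs", "n_channels", "dtype")) {
    if (is.null(meta[[key]])) stop("invalid metadata: missing sidecar key '", key, "'")
  }
  nch <- as.integer(meta$n_channels)
  dtype <- match.arg(meta$dtype, c("int16", "float32"))
  if (!file.exists(path_data)) stop("data file not found: ", path_data)
  nbytes <- file.size(path_data)
  bytes_per <- if (dtype == "int16") 2L else 4L
  n_total <- nbytes / bytes_per
  if (n_total %% nch != 0) stop("truncated file: length not divisible by n_channels")
  con <- file(path_data, "rb")
  on.exit(close(con))
  if (dtype == "int16") {
    if (is.null(meta$scale_uv_per_bit))
      stop("invalid metadata: missing sidecar key 'scale_uv_per_bit'")
    raw_vals <- readBin(con, integer(), n = n_total, size = 2L, endian = "little")
    vals <- raw_vals * as.numeric(meta$scale_uv_per_bit)
  } else {
    vals <- readBin(con, numeric(), n = n_total, size = 4L, endian = "little")
  }
  samples <- matrix(vals, nrow = nch)
  t0 <- if (is.null(meta$t0_s)) 0 else as.numeric(meta$t0_s)
  kind <- if (is.null(meta$kind)) "laminar" else meta$kind
  if (identical(kind, "eeg") && nch == 1L) {
    return(eeg_recording(drop(samples), fs = meta$fs, t0_s = t0))
  }
  spacing <- if (is.null(meta$spacing_um)) 1 else meta$spacing_um
  depth0 <- if (is.null(meta$depth0_um)) 0 else meta$depth0_um
  labels <- if (is.null(meta$layer_labels)) NULL else as.character(meta$layer_labels)
  laminar_recording(samples, fs = meta$fs,
                    probe = probe_geometry(nch, spacing, depth0),
                    layer_labels = labels, t0_s = t0)
}

#' Write a recording as raw binary plus JSON sidecar
#'
#' `float32` mode is lossless; `int16` quantizes by `scale_uv_per_bit`
#' (round-trip error bounded by half a bit).
#'
#' @param rec A [laminar_recording()] or [eeg_recording()].
#' @param path_data,path_meta Output paths for data and sidecar.
#' @param dtype `"float32"` (default) or `"int16"`.
#' @param scale_uv_per_bit Quantization step for int16 mode (microvolts/bit).
#' @return Invisibly, `c(path_data, path_meta)`.
#' @export
write_recording <- function(rec, path_data, path_meta, dtype = c("float32", "int16"),
                            scale_uv_per_bit = 0.195) {
  dtype <- match.arg(dtype)
  if (inherits(rec, "eeg_recording")) {
    samples <- matrix(rec$trace, nrow = 1)
    meta <- list(kind = "eeg", fs = rec$fs, n_channels = 1L, dtype = dtype, t0_s = rec$t0_s)
  } else if (inherits(rec, "laminar_recording")) {
    samples <- rec$samples
    meta <- list(kind = "laminar", fs = rec$fs, n_channels = nrow(samples),
                 dtype = dtype, spacing_um = rec$probe$spacing_um,
                 depth0_um = rec$probe$depth0_um, t0_s = rec$t0_s)
    if (!is.null(rec$layer_labels)) meta$layer_labels <- rec$layer_labels
  } else stop("rec must be a laminar_recording or eeg_recording")
  if (!finite_matrix(samples)) stop("invalid samples: non-finite values")
  con <- tryCatch(file(path_data, "wb"),
                  error = function(e) stop("cannot write data file: ", path_data))
  on.exit(close(con))
  if (dtype == "int16") {
    meta$scale_uv_per_bit <- scale_uv_per_bit
    q <- as.integer(pmax(pmin(round(samples / scale_uv_per_bit), 32767), -32768))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4L, endian = "little")
  }
  jsonlite::write_json(meta, path_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(path_data, path_meta))
}

#' Extract one epoch from a recording
#'
#' Slices the half-open interval `[t_start_s, t_end_s)`; the returned
#' segment's `t0_s` carries the original timebase offset.
#'
#' @param rec A [laminar_recording()] or [eeg_recording()].
#' @param epoch One-row epoch (a list/row with `t_start_s`, `t_end_s`).
#' @return Recording of the same class covering the epoch.
#' @export
extract_epoch <- function(rec, epoch) {
  t0 <- as.numeric(epoch[["t_start_s"]]); t1 <- as.numeric(epoch[["t_end_s"]])
  if (!(t1 > t0)) stop("epoch out of range: zero or negative length")
  fs <- rec$fs
  n <- if (inherits(rec, "eeg_recording")) length(rec$trace) else ncol(rec$samples)
  i0 <- round((t0 - rec$t0_s) * fs) + 1
  i1 <- i0 + round((t1 - t0) * fs) - 1
  if (i0 < 1 || i1 > n) stop("epoch out of range")
  if (inherits(rec, "eeg_recording")) {
    eeg_recording(rec$trace[i0:i1], fs = fs, t0_s = t0)
  } else {
    laminar_recording(rec$samples[, i0:i1, drop = FALSE], fs = fs, probe = rec$probe,
                      layer_labels = rec$layer_labels, t0_s = t0)
  }
}

EVENT_COLUMNS <- c("type", "channel", "t_start_s", "t_peak_s", "t_end_s",
                   "duration_ms", "peak_z")

#' Construct an event table
#'
#' Rows are detected oscillatory events (ripples or spindles), sorted by peak
#' time; overlapping events of the same type are rejected.
#'
#' @param df A data.frame with at least columns `type`, `channel`,
#'   `t_start_s`, `t_peak_s`, `t_end_s`, `duration_ms`, `peak_z`. Extra
#'   feature columns are preserved.
#' @param source Optional list of provenance metadata (recording id, band).
#' @return A `data.frame` with class `event_table`.
#' @export
event_table <- function(df, source = NULL) {
  if (!all(EVENT_COLUMNS %in% names(df))) {
    stop("invalid event table: missing columns ",
         paste(setdiff(EVENT_COLUMNS, names(df)), collapse = ", "))
  }
  df <- as.data.frame(df)
  if (nrow(df) > 0) {
    if (any(df$t_peak_s < df$t_start_s - 1e-9) || any(df$t_end_s < df$t_peak_s - 1e-9))
      stop("invalid event table: t_start <= t_peak <= t_end violated")
    df <- df[order(df$t_peak_s), , drop = FALSE]
    for (tp in unique(df$type)) {
      sub <- df[df$type == tp, , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$t_start_s[-1] < sub$t_end_s[-nrow(sub)] - 1e-9))
        stop("invalid event table: overlapping events of type '", tp, "'")
    }
  }
  rownames(df) <- NULL
  attr(df, "source") <- source
  class(df) <- c("event_table", "data.frame")
  df
}

#' Write / read an event table as CSV
#'
#' Values survive the round trip to at least 6 significant digits.
#'
#' @param table An [event_table()].
#' @param path CSV path.
#' @return `write_event_table` returns `path` invisibly; `read_event_table`
#'   returns an [event_table()].
#' @export
write_event_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(EVENT_COLUMNS %in% names(df)))
    stop("invalid event table: malformed header in ", path)
  event_table(df)
}

#' Write / read an epoch table as CSV (`label,t_start_s,t_end_s`)
#'
#' @param epochs An [epoch_table()].
#' @param path CSV path.
#' @export
write_epochs <- function(epochs, path) {
  utils::write.csv(as.data.frame(epochs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_epochs(df)
}

#' @export
print.laminar_recording <- function(x, ...) {
  cat(sprintf("<laminar_recording> %d channels x %d samples @ %g Hz (%.3f s), spacing %g um\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs,
              x$probe$spacing_um))
  invisible(x)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples @ %g Hz (%.1f s), %d epochs\n",
              length(x$trace), x$fs, length(x$trace) / x$fs,
              if (is.null(x$epochs)) 0L else nrow(x$epochs)))
  invisible(x)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events (%s)\n", nrow(x),
              paste(unique(x$type), collapse = ", ")))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
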