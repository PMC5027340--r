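#' Write / read a multichannel recording
#'
#' The on-disk container is a structured-text header file (`key: value`
#' lines: sampling rate, matrix shape, units, stimulus times, bad channels,
#' quantization, format) pointing at a sibling payload holding the
#' channels x samples matrix, row-major: either 32-bit little-endian floats
#' (`format = "float32"`, default; lossless for 12-bit-quantized signals
#' because the default quantization lattice is exactly representable in
#' float32) or CSV (`format = "csv"`, one row per channel, values printed
#' with 9 significant digits — the declared precision of that dialect).
#'
#' @param recording An [synthesize_recording()] object.
#' @param path Header file path; the payload is written next to it as
#'   `<path>.f32` or `<path>.csv`.
#' @param format `"float32"` or `"csv"`.
#' @return `read_recording` returns an `mea_recording`.
#' @export
write_recording <- function(recording, path, format = c("float32", "csv")) {
  format <- match.arg(format)
  data_file <- paste0(basename(path), if (format == "float32") ".f32" else ".csv")
  hdr <- c(
    sprintf("format: %s", format),
    sprintf("sampling_rate_hz: %.10g", recording$sampling_rate_hz),
    sprintf("n_channels: %d", nrow(recording$signal)),
    sprintf("n_samples: %d", ncol(recording$signal)),
    sprintf("units: %s", recording$units),
    sprintf("stimulus_times_ms: %s", paste(recording$stimulus_times_ms, collapse = ",")),
    sprintf("bad_channels: %s", paste(recording$geometry$bad_channels, collapse = ",")),
    sprintf("quantization_bits: %s", as.character(recording$quantization_bits)),
    sprintf("range_mv: %.10g", recording$range_mv),
    sprintf("geometry_rows: %d", recording$geometry$rows),
    sprintf("geometry_cols: %d", recording$geometry$cols),
    sprintf("pitch_mm: %.10g", recording$geometry$pitch_mm),
    sprintf("data_file: %s", data_file)
  )
  writeLines(hdr, path)
  payload <- file.path(dirname(path), data_file)
  if (format == "float32") {
    con <- file(payload, "wb")
    on.exit(close(con))
    writeBin(as.numeric(t(recording$signal)), con, size = 4L, endian = "little")
  } else {
    utils::write.table(format(recording$signal, digits = 9, trim = TRUE,
                              scientific = TRUE),
                       payload, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

parse_header <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([a-z_]+): ?(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop_format("malformed header line: '%s'", lines[bad][1])
  stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, "", 2))
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_format("recording header not found: %s", path)
  h <- parse_header(path)
  need <- c("format", "sampling_rate_hz", "n_channels", "n_samples", "units",
            "stimulus_times_ms", "data_file")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop_format("recording header missing field(s): %s", toString(miss))
  n_ch <- as.integer(h$n_channels); n_samp <- as.integer(h$n_samples)
  payload <- file.path(dirname(path), h$data_file)
  if (!file.exists(payload)) stop_format("payload file not found: %s", payload)
  if (identical(h$format, "float32")) {
    con <- file(payload, "rb")
    on.exit(close(con))
    vals <- readBin(con, "numeric", n = n_ch * n_samp + 1L, size = 4L, endian = "little")
    if (length(vals) != n_ch * n_samp) {
      stop_format("payload size mismatch: n_channels x n_samples = %d but file holds %d values",
                  n_ch * n_samp, length(vals))
    }
    signal <- matrix(vals, nrow = n_ch, byrow = TRUE)
  } else if (identical(h$format, "csv")) {
    signal <- as.matrix(utils::read.table(payload, sep = ",", header = FALSE))
    dimnames(signal) <- NULL
    if (nrow(signal) != n_ch || ncol(signal) != n_samp) {
      stop_format("payload shape mismatch: header says %d x %d, file is %d x %d",
                  n_ch, n_samp, nrow(signal), ncol(signal))
    }
  } else {
    stop_format("unknown recording format '%s'", h$format)
  }
  bad <- if (nzchar(h$bad_channels %||% "")) as.integer(strsplit(h$bad_channels, ",")[[1]]) else integer()
  geometry <- make_geometry(as.integer(h$geometry_rows %||% 2L),
                            as.integer(h$geometry_cols %||% 2L),
                            as.numeric(h$pitch_mm %||% 2.7),
                            bad_channels = bad)
  if (nrow(geometry$channels) != n_ch) {
    stop_format("header geometry (%d channels) inconsistent with n_channels = %d",
                nrow(geometry$channels), n_ch)
  }
  qb <- suppressWarnings(as.integer(h$quantization_bits %||% NA))
  structure(list(signal = signal,
                 sampling_rate_hz = as.numeric(h$sampling_rate_hz),
                 stimulus_times_ms = as.numeric(strsplit(h$stimulus_times_ms, ",")[[1]]),
                 geometry = geometry,
                 ari_ms = NA_real_, noise_sd_mv = NA_real_,
                 quantization_bits = qb,
                 range_mv = as.numeric(h$range_mv %||% NA),
                 seed = NA_integer_, units = h$units),
            class = "mea_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
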