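# Minimal European Data Format (EDF, 16-bit) support: enough to ingest a
# standard continuous clinical recording and to write round-trip test files.
# Annotation signals ("EDF Annotations") are skipped on read.

read_ascii <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

#' Read a continuous EEG recording from an EDF file
#'
#' Supports the standard 16-bit EDF layout: a 256-byte main header, one
#' 256-byte header block per signal, and little-endian 16-bit data records.
#' Digital values are mapped to physical units with each signal's
#' digital/physical min/max calibration. All retained signals must share one
#' sampling rate.
#'
#' @param path Path to the EDF file.
#' @return A [continuous_eeg()] (units as calibrated in the file; clinical
#'   EEG is microvolts).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8L)
  if (!identical(version, "0")) stop("not an EDF file (version != 0)", call. = FALSE)
  invisible(readChar(con, 80L + 80L + 8L + 8L, useBytes = TRUE))
  invisible(read_ascii(con, 8L))                       # header length
  invisible(readChar(con, 44L, useBytes = TRUE))       # reserved
  n_records <- as.integer(read_ascii(con, 8L))
  record_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))

  field <- function(width) vapply(seq_len(ns), function(i) {
    read_ascii(con, width)
  }, character(1))
  labels <- field(16L)
  invisible(field(80L))                                # transducer
  invisible(field(8L))                                 # physical dimension
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  invisible(field(80L))                                # prefiltering
  spr <- as.integer(field(8L))                         # samples per record
  invisible(field(32L))                                # reserved

  per_rec <- sum(spr)
  raw <- readBin(con, "integer", n = per_rec * n_records, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < per_rec * n_records) stop("truncated EDF data", call. = FALSE)
  mat <- matrix(raw, nrow = per_rec)                   # one column per record
  offsets <- cumsum(c(0L, spr))
  keep <- which(labels != "EDF Annotations")
  if (length(keep) == 0) stop("no data signals in EDF file", call. = FALSE)
  rates <- spr[keep] / record_dur
  if (length(unique(rates)) != 1) {
    stop("signals with mixed sampling rates are not supported", call. = FALSE)
  }
  data <- matrix(0, nrow = length(keep), ncol = spr[keep[1]] * n_records)
  for (j in seq_along(keep)) {
    i <- keep[j]
    dig <- as.numeric(mat[(offsets[i] + 1L):offsets[i + 1L], ])
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    data[j, ] <- (dig - dig_min[i]) * gain + phys_min[i]
  }
  continuous_eeg(data, rates[1], sub("^EEG ", "", labels[keep]))
}

#' Write a continuous recording as a 16-bit EDF file
#'
#' Companion to [read_edf()], mainly for building test recordings. Uses
#' one-second data records; the recording is zero-padded to a whole number
#' of records (the sampling rate must be an integer). Calibration spans the
#' symmetric physical range covering the data.
#'
#' @param eeg A [continuous_eeg()].
#' @param path Output path.
#' @param phys_range Physical calibration half-range; defaults to the
#'   smallest integer covering `max(abs(data))`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path, phys_range = NULL) {
  stopifnot(inherits(eeg, "continuous_eeg"), eeg$rate == round(eeg$rate))
  nc <- nrow(eeg$data)
  spr <- as.integer(eeg$rate)
  n_records <- as.integer(ceiling(ncol(eeg$data) / spr))
  padded <- matrix(0, nc, spr * n_records)
  padded[, seq_len(ncol(eeg$data))] <- eeg$data
  if (is.null(phys_range)) phys_range <- max(1, ceiling(max(abs(eeg$data))))
  dig_min <- -32768; dig_max <- 32767
  gain <- (2 * phys_range) / (dig_max - dig_min)
  dig <- round_half_away((padded + phys_range) / gain) + dig_min
  dig <- pmax(dig_min, pmin(dig_max, dig))

  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, width) {
    s <- formatC(as.character(x), width = -width)
    writeChar(substr(s, 1L, width), con, eos = NULL)
  }
  pad("0", 8L)                                  # version
  pad("X X X X", 80L); pad("Startdate X X X X", 80L)
  pad("01.01.20", 8L); pad("00.00.00", 8L)
  pad(256L * (1L + nc), 8L)                     # header bytes
  pad("", 44L)
  pad(n_records, 8L)
  pad("1", 8L)                                  # record duration, s
  pad(nc, 4L)
  for (ch in eeg$channels) pad(paste("EEG", ch), 16L)
  for (i in seq_len(nc)) pad("", 80L)
  for (i in seq_len(nc)) pad("uV", 8L)
  for (i in seq_len(nc)) pad(-phys_range, 8L)
  for (i in seq_len(nc)) pad(phys_range, 8L)
  for (i in seq_len(nc)) pad(dig_min, 8L)
  for (i in seq_len(nc)) pad(dig_max, 8L)
  for (i in seq_len(nc)) pad("", 80L)
  for (i in seq_len(nc)) pad(spr, 8L)           # samples per record
  for (i in seq_len(nc)) pad("", 32L)
  # record layout: for each record, each signal's spr samples contiguously
  arr <- aperm(array(dig, dim = c(nc, spr, n_records)), c(2, 1, 3))
  writeBin(as.integer(arr), con, size = 2L, endian = "little")
  invisible(path)
}
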