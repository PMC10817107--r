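# Recording and annotation I/O.
#
# EDF support is a minimal self-contained implementation of the European
# Data Format essentials (ASCII header, 16-bit little-endian integer
# samples with physical scaling, 1-second data records); enough for
# polysomnography-style continuous multi-channel EEG. EDF+ annotations and
# discontinuous records are out of scope.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers with per-channel physical
#' scaling (the round-trip error is bounded by the channel's peak-to-peak
#' range divided by 65535). The sampling rate must be a positive integer
#' and the recording is truncated to a whole number of seconds (1-s data
#' records).
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9 || fs < 1) {
    stop("EDF writer requires an integer sampling rate, got fs = ", fs,
         call. = FALSE)
  }
  fs <- as.integer(round(fs))
  ns <- nrow(rec$samples)
  n_rec <- ncol(rec$samples) %/% fs
  if (n_rec < 1) stop("recording shorter than one 1-s data record", call. = FALSE)
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)                       # version
  wr("X X X X", 80)                # patient id (anonymous)
  wr("Startdate 01-JAN-2020 X X X", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8)
  wr("", 44)                       # reserved
  wr(as.character(n_rec), 8)
  wr("1", 8)                       # record duration, seconds
  wr(as.character(ns), 4)
  for (ch in rec$channel_names) wr(ch, 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(formatC(pmin_[i], format = "g", digits = 7), 8)
  for (i in seq_len(ns)) wr(formatC(pmax_[i], format = "g", digits = 7), 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)        # prefiltering
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)        # reserved

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      d <- as.integer(round((x[i, idx] - pmin_[i]) * scale[i] + dmin))
      writeBin(pmin(dmax, pmax(dmin, d)), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                            # header bytes (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("EDF header: bad signal count", call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    stop("EDF reader supports a common sampling rate only; ",
         "samples-per-record differ across signals", call. = FALSE)
  }
  if (is.na(dur) || dur <= 0) stop("EDF header: bad record duration", call. = FALSE)
  fs <- spr[1] / dur
  samples <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE,
                   endian = "little")
      if (length(d) != spr[1]) stop("EDF file truncated", call. = FALSE)
      samples[i, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        (d - dmin[i]) * scale[i] + pmin_[i]
    }
  }
  rownames(samples) <- labels
  new_eeg_recording(samples, fs, labels)
}

#' Write a recording as CSV plus JSON header
#'
#' Plain-text fallback format: `<path>` is a CSV with one column per
#' channel, and `<path>.json` holds the sampling rate and channel names.
#'
#' @param rec An `eeg_recording`.
#' @param path CSV file path (a sidecar `<path>.json` is written next to it).
#' @return Invisibly, `path`.
#' @export
write_csv_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(t(rec$samples))
  names(df) <- rec$channel_names
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_names = rec$channel_names),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

read_csv_recording <- function(path) {
  header_path <- paste0(path, ".json")
  if (!file.exists(header_path)) {
    stop("missing JSON header file: ", header_path, call. = FALSE)
  }
  hdr <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  if (is.null(hdr$fs)) {
    stop("JSON header is missing required field 'fs'", call. = FALSE)
  }
  if (is.null(hdr$channel_names)) {
    stop("JSON header is missing required field 'channel_names'",
         call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) != length(hdr$channel_names)) {
    stop("CSV has ", ncol(df), " channel column(s) but the header names ",
         length(hdr$channel_names), call. = FALSE)
  }
  if (anyNA(df)) {
    stop("CSV channels have unequal lengths (missing values found)",
         call. = FALSE)
  }
  new_eeg_recording(t(as.matrix(df)), hdr$fs, hdr$channel_names)
}

#' Read a recording from disk
#'
#' @param path File path.
#' @param format `"edf"` or `"csv_header"` (CSV with a `<path>.json`
#'   sidecar holding `fs` and `channel_names`).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("edf", "csv_header")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- match.arg(format)
  switch(format, edf = read_edf(path), csv_header = read_csv_recording(path))
}

#' Write a recording to disk
#'
#' @inheritParams read_recording
#' @param rec An `eeg_recording`.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, format = c("edf", "csv_header")) {
  format <- match.arg(format)
  switch(format, edf = write_edf(rec, path),
         csv_header = write_csv_recording(rec, path))
}

#' Read per-epoch stage annotations
#'
#' One stage token per line, case-insensitive, with `R` accepted as an
#' alias for `REM`. Epoch indices are assigned 0-based in file order.
#'
#' @param path Text file path.
#' @return Tibble with columns `epoch_index` (0-based integer) and `stage`
#'   (factor).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  while (length(lines) > 0 && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]           # trailing blank lines only
  }
  ok <- toupper(lines) %in% c(stage_levels(), "R")
  if (any(!ok)) {
    stop("unknown stage token '", lines[!ok][1], "' at line ",
         which(!ok)[1], call. = FALSE)
  }
  tibble::tibble(epoch_index = seq_along(lines) - 1L,
                 stage = stage_factor(lines))
}

#' Write per-epoch stage annotations
#'
#' Always writes full tokens (`REM`, never `R`), one per line.
#'
#' @param stages Stage tokens or factor.
#' @param path Output text file path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(stages, path) {
  writeLines(as.character(stage_factor(stages)), path)
  invisible(path)
}
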