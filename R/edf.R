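# Minimal European Data Format (EDF) I/O.
#
# EDF stores a fixed-layout ASCII header (256 bytes + 256 per signal) followed
# by data records of little-endian 16-bit integers, scaled per signal from
# digital to physical range. Only the continuous, equal-rate layout used for
# routine clinical EEG is supported: every signal must have the same number of
# samples per record.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Read a European Data Format (EDF) file
#'
#' Parses the fixed ASCII header and the int16 data records and returns the
#' physically scaled signals. All signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @return an [new_recording()] object.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  if (nchar(hdr) < 256L) format_error("truncated EDF header")
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1L))
  n_records <- as.integer(fld(237, 8))
  record_dur <- as.numeric(fld(245, 8))
  ns <- as.integer(fld(253, 4))
  if (is.na(ns) || ns < 1L || is.na(n_records) || n_records < 1L) {
    format_error("unparseable EDF header (signal or record count)")
  }
  sig <- rawToChar(readBin(con, "raw", 256L * ns))
  # byte offsets of each field group within the signal header, EDF field order
  off <- c(label = 0L, transducer = 16L, dim = 96L, pmin = 104L, pmax = 112L,
           dmin = 120L, dmax = 128L, prefilter = 136L, nsamp = 216L)
  grab <- function(name, len) {
    vapply(seq_len(ns), function(i) {
      start <- off[[name]] * ns + (i - 1L) * len + 1L
      trimws(substr(sig, start, start + len - 1L))
    }, character(1))
  }
  labels <- grab("label", 16)
  pmin <- as.numeric(grab("pmin", 8))
  pmax <- as.numeric(grab("pmax", 8))
  dmin <- as.numeric(grab("dmin", 8))
  dmax <- as.numeric(grab("dmax", 8))
  nsamp <- as.integer(grab("nsamp", 8))
  if (length(unique(nsamp)) != 1L) {
    format_error("EDF signals with differing per-record sample counts are not supported")
  }
  nr <- nsamp[1]
  fs <- nr / record_dur
  data <- matrix(0, nrow = ns, ncol = nr * n_records)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = nr * ns, size = 2L, endian = "little")
    if (length(block) < nr * ns) format_error("truncated EDF data record")
    cols <- ((r - 1L) * nr + 1L):(r * nr)
    for (i in seq_len(ns)) {
      d <- block[((i - 1L) * nr + 1L):(i * nr)]
      data[i, cols] <- (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
    }
  }
  new_recording(data, labels, fs)
}

#' Write a European Data Format (EDF) file
#'
#' Quantizes each channel to the 16-bit digital range over its physical
#' min/max and writes 1-second data records (the trailing partial second is
#' dropped, as EDF records must be complete).
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) config_error("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_records <- floor(ncol(rec$data) / fs)
  if (n_records < 1L) contract_error("recording shorter than one EDF record (1 s)")
  x <- rec$data[, seq_len(n_records * fs), drop = FALSE]
  pmin <- apply(x, 1, min)
  pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(rec$subject_id, 80), edf_pad("eegdloc", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8), edf_pad("", 44),
    edf_pad(n_records, 8), edf_num(1, 8), edf_pad(ns, 4)
  )
  shdr <- paste0(
    paste(vapply(rec$channel_labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_num(dmin, 8), ns), collapse = ""),
    paste(rep(edf_num(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, shdr), con, eos = NULL)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- integer(0)
    for (i in seq_len(ns)) {
      d <- round((x[i, cols] - pmin[i]) / (pmax[i] - pmin[i]) * (dmax - dmin) + dmin)
      block <- c(block, as.integer(pmin(pmax(d, dmin), dmax)))
    }
    writeBin(block, con, size = 2L, endian = "little")
  }
  invisible(path)
}
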