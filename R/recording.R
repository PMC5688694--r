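#' Construct a multichannel EEG recording
#'
#' The central container of the package: a channels x samples numeric matrix
#' with ordered channel labels, a sampling rate, and optional artifact
#' annotations as half-open `[start_s, end_s)` intervals in seconds
#' (0-based time origin). Artifact intervals are canonicalized on
#' construction: sorted, merged where overlapping, and clipped to the record
#' duration.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param channel_labels character vector, one label per row of `data`.
#' @param fs sampling rate in Hz.
#' @param subject_id opaque subject identifier.
#' @param artifact_intervals two-column matrix (start_s, end_s) or NULL.
#' @param meta optional list of provenance (e.g. generator parameters).
#' @return object of class `eeg_recording`.
#' @export
new_recording <- function(data, channel_labels, fs, subject_id = "anon",
                          artifact_intervals = NULL, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    contract_error("`data` must be a numeric channels x samples matrix")
  }
  if (length(channel_labels) != nrow(data)) {
    contract_error("one channel label per data row is required")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    config_error("`fs` must be a single positive sampling rate in Hz")
  }
  dur <- ncol(data) / fs
  ai <- canonicalize_intervals(artifact_intervals, dur)
  structure(
    list(
      subject_id = as.character(subject_id),
      channel_labels = as.character(channel_labels),
      data = data,
      fs = fs,
      artifact_intervals = ai,
      meta = meta
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s), %d artifact interval(s)\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    nrow(x$artifact_intervals)
  ))
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$data) / rec$fs

# Sort, merge overlapping/abutting, clip to [0, duration]. Returns a 2-column
# matrix (possibly 0-row) with columns start_s, end_s.
canonicalize_intervals <- function(intervals, duration) {
  if (is.null(intervals) || NROW(intervals) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start_s", "end_s"))))
  }
  m <- matrix(as.numeric(as.matrix(intervals)), ncol = 2)
  if (any(!is.finite(m))) contract_error("artifact intervals must be finite")
  if (any(m[, 2] <= m[, 1])) {
    contract_error("artifact intervals must satisfy start_s < end_s")
  }
  m[, 1] <- pmax(m[, 1], 0)
  m[, 2] <- pmin(m[, 2], duration)
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (nrow(m) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start_s", "end_s"))))
  }
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      k <- nrow(out)
      if (m[i, 1] <= out[k, 2]) {
        out[k, 2] <- max(out[k, 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  dimnames(out) <- list(NULL, c("start_s", "end_s"))
  out
}

#' Read a recording from disk
#'
#' Supports European Data Format (`format = "edf"`) and plain delimited text
#' (`format = "delimited"`): one column per channel with a header row of
#' channel labels. Delimited files carry no sampling rate, so `fs_hint` is
#' required for them.
#'
#' @param path file path.
#' @param format `"edf"` or `"delimited"`.
#' @param fs_hint sampling rate in Hz (required for delimited input).
#' @param subject_id identifier attached to the recording; defaults to the
#'   file name without extension.
#' @param artifact_path optional two-column delimited file (start_s, end_s)
#'   of artifact annotations.
#' @return an [new_recording()] object.
#' @export
read_recording <- function(path, format = c("edf", "delimited"), fs_hint = NULL,
                           subject_id = NULL, artifact_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "edf") {
    rec <- read_edf(path)
    rec$subject_id <- as.character(subject_id)
  } else {
    if (is.null(fs_hint)) {
      config_error("delimited recordings carry no sampling rate; supply `fs_hint`")
    }
    tab <- tryCatch(
      read.table(path, header = TRUE, sep = "\t", check.names = FALSE),
      error = function(e) format_error(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
    )
    if (ncol(tab) < 1L || nrow(tab) < 1L) format_error("empty delimited recording")
    rec <- new_recording(
      data = t(as.matrix(tab)),
      channel_labels = colnames(tab),
      fs = fs_hint,
      subject_id = subject_id
    )
  }
  if (!is.null(artifact_path)) {
    rec$artifact_intervals <- canonicalize_intervals(
      read_artifact_annotations(artifact_path), recording_duration(rec)
    )
  }
  rec
}

#' Write a recording as delimited text
#'
#' One column per channel, tab-separated, with a header row of channel
#' labels. The inverse of `read_recording(format = "delimited")`.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_delimited <- function(rec, path) {
  tab <- as.data.frame(t(rec$data))
  colnames(tab) <- rec$channel_labels
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read artifact annotations
#'
#' Two-column delimited file of half-open intervals (start_s, end_s), with or
#' without a header row.
#'
#' @param path file path.
#' @return two-column numeric matrix.
#' @export
read_artifact_annotations <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^[-0-9.eE+\\s,\t]+$", first, perl = TRUE)
  tab <- read.table(path, header = has_header, sep = "", check.names = FALSE)
  if (ncol(tab) != 2L) format_error("artifact annotation files need exactly two columns")
  as.matrix(tab)
}
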