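# Preprocessing: bipolar montage, resampling, artifact exclusion,
# normalization, lowpass filtering, and segmentation into trials/epochs.

#' Standard 18-pair longitudinal bipolar montage
#'
#' The double-banana bipolar derivation over the 10-20 electrode placement:
#' FP1-F7, F7-T7, T7-P7, P7-O1, FP1-F3, F3-C3, C3-P3, P3-O1, FZ-CZ, CZ-PZ,
#' FP2-F4, F4-C4, C4-P4, P4-O2, FP2-F8, F8-T8, T8-P8, P8-O2.
#'
#' @return two-column character matrix (anode, cathode) with 18 rows.
#' @export
default_bipolar_montage <- function() {
  pairs <- c(
    "FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FZ-CZ", "CZ-PZ",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2"
  )
  m <- do.call(rbind, strsplit(pairs, "-", fixed = TRUE))
  dimnames(m) <- list(pairs, c("anode", "cathode"))
  m
}

#' Apply a bipolar montage
#'
#' Re-references a referential recording into bipolar channels: output channel
#' i is the samplewise difference anode_i - cathode_i. Electrode labels are
#' matched case-insensitively.
#'
#' @param rec an `eeg_recording` with referential electrode channels.
#' @param montage two-column (anode, cathode) character matrix; defaults to
#'   [default_bipolar_montage()].
#' @return an `eeg_recording` whose channels follow the montage order, with
#'   labels `"ANODE-CATHODE"`.
#' @export
apply_bipolar_montage <- function(rec, montage = default_bipolar_montage()) {
  montage <- as.matrix(montage)
  have <- toupper(rec$channel_labels)
  idx_of <- function(lab) {
    i <- match(toupper(lab), have)
    if (is.na(i)) {
      stop_eegdloc(sprintf("montage electrode '%s' not present in recording", lab),
                   "eegdloc_montage_error")
    }
    i
  }
  a <- vapply(montage[, 1], idx_of, integer(1))
  c_ <- vapply(montage[, 2], idx_of, integer(1))
  out <- rec$data[a, , drop = FALSE] - rec$data[c_, , drop = FALSE]
  new_recording(
    out, paste(toupper(montage[, 1]), toupper(montage[, 2]), sep = "-"),
    rec$fs, rec$subject_id, rec$artifact_intervals, rec$meta
  )
}

#' Downsample a recording to 250 Hz
#'
#' Recordings at 250 Hz pass through unchanged; 500 Hz recordings are
#' decimated by 2 with an anti-aliasing lowpass (polyphase IIR decimation),
#' preserving duration to within one sample. Other rates are rejected.
#'
#' @param rec an `eeg_recording` with `fs` 250 or 500.
#' @return an `eeg_recording` at 250 Hz.
#' @export
resample_to_250 <- function(rec) {
  if (rec$fs == 250) return(rec)
  if (rec$fs != 500) {
    config_error(sprintf("unsupported sampling rate %g Hz (need 250 or 500)", rec$fs))
  }
  out <- t(apply(rec$data, 1, function(x) signal::decimate(x, 2)))
  new_recording(out, rec$channel_labels, 250, rec$subject_id,
                rec$artifact_intervals, rec$meta)
}

#' Artifact-free sample spans
#'
#' Complements the (canonicalized) artifact intervals over the record,
#' returning the maximal contiguous artifact-free spans as half-open sample
#' index ranges. With no annotations the whole record is one span.
#'
#' @param rec an `eeg_recording`.
#' @return two-column integer matrix (`start`, `end`): 1-based start sample,
#'   exclusive end, i.e. samples `start .. end - 1` are artifact-free.
#' @export
exclude_artifacts <- function(rec) {
  n <- ncol(rec$data)
  fs <- rec$fs
  ai <- rec$artifact_intervals
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (nrow(ai) == 0L) {
    return(matrix(c(1L, n + 1L), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  # sample i covers time [(i-1)/fs, i/fs); it is an artifact sample when its
  # timestamp (i-1)/fs falls inside an artifact interval
  a_start <- floor(ai[, 1] * fs) + 1L
  a_end <- ceiling(ai[, 2] * fs) + 1L # exclusive
  a_start <- pmax(a_start, 1L)
  a_end <- pmin(a_end, n + 1L)
  spans <- list()
  cursor <- 1L
  for (k in seq_along(a_start)) {
    if (a_start[k] > cursor) spans[[length(spans) + 1L]] <- c(cursor, a_start[k])
    cursor <- max(cursor, a_end[k])
  }
  if (cursor <= n) spans[[length(spans) + 1L]] <- c(cursor, n + 1L)
  if (length(spans) == 0L) return(empty)
  out <- do.call(rbind, spans)
  storage.mode(out) <- "integer"
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Normalize each channel to zero mean, unit variance
#'
#' Statistics are computed over artifact-free samples only (artifact spans are
#' excluded from all analysis) and applied to the full channel. A channel with
#' (near-)zero variance over the retained samples raises a degenerate-channel
#' error rather than passing silently.
#'
#' @param rec an `eeg_recording`.
#' @return the normalized `eeg_recording`.
#' @export
zscore_channels <- function(rec) {
  spans <- exclude_artifacts(rec)
  keep <- unlist(lapply(seq_len(nrow(spans)), function(i) {
    seq.int(spans[i, 1], spans[i, 2] - 1L)
  }))
  if (length(keep) < 2L) contract_error("fewer than two artifact-free samples")
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    x <- out[i, keep]
    s <- sd(x)
    if (!is.finite(s) || s < 1e-12) {
      degenerate_channel_error(sprintf(
        "channel '%s' has zero variance over artifact-free samples",
        rec$channel_labels[i]
      ))
    }
    out[i, ] <- (out[i, ] - mean(x)) / s
  }
  new_recording(out, rec$channel_labels, rec$fs, rec$subject_id,
                rec$artifact_intervals, rec$meta)
}

# Filter coefficients are fixed by the analysis design: 10th-order Chebyshev
# type I, 0.5 dB passband ripple, 50 Hz cutoff at fs = 250.
chebyshev_lowpass <- function(order = 10, ripple_db = 0.5, cutoff_hz = 50, fs = 250) {
  signal::cheby1(order, ripple_db, W = cutoff_hz / (fs / 2), type = "low")
}

#' Zero-phase Chebyshev lowpass filter
#'
#' Applies a 10th-order Chebyshev type I lowpass (0.5 dB passband ripple,
#' 50 Hz cutoff) forward and backward (zero phase, no group delay; effective
#' stopband attenuation is doubled). Requires the post-downsampling rate of
#' 250 Hz.
#'
#' @param rec an `eeg_recording` at 250 Hz.
#' @param order,ripple_db,cutoff_hz filter design parameters.
#' @return the filtered `eeg_recording`, same sample count.
#' @export
lowpass_filter <- function(rec, order = 10, ripple_db = 0.5, cutoff_hz = 50) {
  if (rec$fs != 250) {
    config_error("lowpass filter is designed for fs = 250 Hz; downsample first")
  }
  cf <- chebyshev_lowpass(order, ripple_db, cutoff_hz, rec$fs)
  # The Chebyshev passband ripple attenuates DC and filtfilt edge transients
  # perturb it further; filter the demeaned signal and restore the channel
  # mean exactly, so filtering never shifts it.
  out <- t(apply(rec$data, 1, function(x) {
    m <- mean(x)
    y <- signal::filtfilt(cf, x - m)
    y - mean(y) + m
  }))
  new_recording(out, rec$channel_labels, rec$fs, rec$subject_id,
                rec$artifact_intervals, rec$meta)
}

#' Segmentation plan
#'
#' @param epoch_len_s epoch length in seconds (default 5).
#' @param n_epochs_per_trial epochs per trial (default 40, i.e. 200 s trials),
#'   or the sentinel `"all"` for a single trial holding every complete epoch.
#' @return a `segmentation_plan` list.
#' @export
segmentation_plan <- function(epoch_len_s = 5, n_epochs_per_trial = 40) {
  if (!is.numeric(epoch_len_s) || epoch_len_s <= 0) {
    config_error("epoch_len_s must be positive")
  }
  all_epochs <- identical(n_epochs_per_trial, "all")
  if (!all_epochs && (!is.numeric(n_epochs_per_trial) || n_epochs_per_trial < 1)) {
    config_error("n_epochs_per_trial must be a positive integer or \"all\"")
  }
  structure(list(epoch_len_s = epoch_len_s,
                 n_epochs_per_trial = if (all_epochs) "all" else as.integer(n_epochs_per_trial)),
            class = "segmentation_plan")
}

#' Segment a recording into trials of non-overlapping epochs
#'
#' Epochs tile each artifact-free span from its start; an incomplete trailing
#' epoch within a span is discarded, and epochs never straddle an artifact.
#' Consecutive epochs are grouped `n_epochs_per_trial` at a time into trials;
#' a trailing group too small to form a trial is discarded. With
#' `n_epochs_per_trial = "all"` the recording yields a single trial containing
#' every complete epoch.
#'
#' @param rec a preprocessed `eeg_recording`.
#' @param plan a [segmentation_plan()].
#' @return list of trials; each trial is a list with `subject_id`,
#'   `trial_index`, and `epochs` (a list of channels x samples matrices).
#'   A recording shorter than one epoch yields an empty list with a warning.
#' @export
segment <- function(rec, plan = segmentation_plan()) {
  ep_n <- as.integer(round(plan$epoch_len_s * rec$fs))
  spans <- exclude_artifacts(rec)
  epochs <- list()
  for (i in seq_len(nrow(spans))) {
    len <- spans[i, 2] - spans[i, 1]
    k <- len %/% ep_n
    if (k < 1L) next
    for (j in seq_len(k)) {
      s0 <- spans[i, 1] + (j - 1L) * ep_n
      epochs[[length(epochs) + 1L]] <- rec$data[, s0:(s0 + ep_n - 1L), drop = FALSE]
    }
  }
  if (length(epochs) == 0L) {
    warning(sprintf("recording %s shorter than one %gs epoch; no trials",
                    rec$subject_id, plan$epoch_len_s))
    return(list())
  }
  per <- if (identical(plan$n_epochs_per_trial, "all")) {
    length(epochs)
  } else {
    plan$n_epochs_per_trial
  }
  n_trials <- length(epochs) %/% per
  lapply(seq_len(n_trials), function(t) {
    list(
      subject_id = rec$subject_id,
      trial_index = t,
      epochs = epochs[((t - 1L) * per + 1L):(t * per)]
    )
  })
}

#' Full preprocessing chain
#'
#' Applies, in order: downsampling to 250 Hz, bipolar montage (skipped when
#' the recording already carries the 18 bipolar channels or
#' `montage = NULL`), per-channel normalization over artifact-free samples,
#' and the zero-phase 50 Hz Chebyshev lowpass.
#'
#' @param rec raw `eeg_recording`.
#' @param montage bipolar montage matrix, `"auto"` (default: apply the
#'   standard montage unless channels already look bipolar), or `NULL` to
#'   skip re-referencing.
#' @param filter logical; apply the lowpass stage (default TRUE).
#' @return preprocessed `eeg_recording` at 250 Hz.
#' @export
preprocess_recording <- function(rec, montage = "auto", filter = TRUE) {
  rec <- resample_to_250(rec)
  apply_m <- if (identical(montage, "auto")) {
    !all(grepl("-", rec$channel_labels, fixed = TRUE))
  } else {
    !is.null(montage)
  }
  if (apply_m) {
    m <- if (identical(montage, "auto") || is.null(montage)) default_bipolar_montage() else montage
    rec <- apply_bipolar_montage(rec, m)
  }
  rec <- zscore_channels(rec)
  if (filter) rec <- lowpass_filter(rec)
  rec
}
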