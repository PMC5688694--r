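# The 25-feature time-series suite computed per epoch, plus epoch-to-trial
# aggregation. Features f1-f3 are joint (multichannel MVAR eigenvalues);
# f4-f25 are computed per channel and averaged across channels.

#' Default feature-extraction configuration
#'
#' @param eig_threshold modulus threshold for the slow-mode count f3.
#' @param ami_bins number of marginal bins for auto-mutual information.
#' @param ami_max_lag largest AMI lag in samples (0.2 s at 250 Hz).
#' @param bicor_lags lags (samples) averaged in the bicorrelation feature.
#' @param cpei_tie_threshold absolute-difference threshold below which two
#'   samples count as tied in the ordinal-pattern features (on normalized
#'   data, ties arise essentially only from clipping/quantization).
#' @param bands 2-column matrix of band edges in Hz, rows named
#'   delta/theta/alpha/beta/gamma.
#' @return list of feature parameters.
#' @export
feature_config <- function(eig_threshold = 0.95, ami_bins = 16L,
                           ami_max_lag = 50L, bicor_lags = 1:20,
                           cpei_tie_threshold = 1e-6, bands = eeg_bands()) {
  list(
    mvar_order = 1L,
    eig_threshold = eig_threshold,
    ami_bins = as.integer(ami_bins),
    ami_max_lag = as.integer(ami_max_lag),
    bicor_lags = as.integer(bicor_lags),
    cpei_tie_threshold = cpei_tie_threshold,
    bands = bands
  )
}

#' Clinical EEG frequency bands
#'
#' Standard band edges, with gamma capped at the 50 Hz lowpass cutoff:
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-50 Hz.
#'
#' @return 5 x 2 numeric matrix of band edges (Hz).
#' @export
eeg_bands <- function() {
  m <- rbind(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
             beta = c(13, 30), gamma = c(30, 50))
  colnames(m) <- c("lo", "hi")
  m
}

#' Feature identifiers and descriptions
#'
#' @return data.frame with columns `id` (f1..f25) and `description`.
#' @export
feature_table <- function() {
  data.frame(
    id = paste0("f", 1:25),
    description = c(
      "max |eigenvalue| of MVAR(1) coefficient matrix",
      "min |eigenvalue| of MVAR(1) coefficient matrix",
      "count of |eigenvalues| > 0.95",
      "variance", "skewness", "kurtosis (non-excess)",
      "delta band power", "theta band power", "alpha band power",
      "beta band power", "gamma band power",
      "(beta+gamma)/total power", "(delta+theta)/total power",
      "Hurst exponent (R/S)", "Hjorth complexity",
      "equidistant auto-mutual information at lag 1",
      "equiprobable auto-mutual information at lag 1",
      "first minimum lag of equidistant AMI",
      "first minimum lag of equiprobable AMI",
      "bicorrelation (mean over lags 1-20)",
      "median frequency (Hz)",
      "Spearman lag-1 autocorrelation",
      "Pearson lag-1 autocorrelation",
      "partial autocorrelation at lag 2",
      "composite permutation entropy index (CPEI)"
    ),
    stringsAsFactors = FALSE
  )
}

check_series <- function(x, min_len = 2L, what = "series") {
  if (!is.numeric(x)) contract_error(sprintf("%s must be numeric", what))
  if (length(x) < min_len) {
    contract_error(sprintf("%s needs at least %d samples", what, min_len))
  }
  if (any(!is.finite(x))) contract_error(sprintf("%s contains non-finite values", what))
  invisible(x)
}

check_nondegenerate <- function(x) {
  if (max(x) - min(x) < 1e-12) {
    degenerate_channel_error("constant (zero-variance) channel")
  }
  invisible(x)
}

## ---- moments --------------------------------------------------------------

#' Variance, skewness and kurtosis
#'
#' Sample variance (n-1 denominator); skewness and kurtosis as standardized
#' third and fourth central moments with population (1/n) moment estimates.
#' Kurtosis is non-excess (Gaussian value 3).
#'
#' @param x numeric series, length >= 4.
#' @return named vector `c(variance, skewness, kurtosis)`.
#' @export
moment_features <- function(x) {
  check_series(x, 4L)
  check_nondegenerate(x)
  d <- x - mean(x)
  m2 <- mean(d^2)
  c(variance = var(x),
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2)
}

## ---- spectral features ----------------------------------------------------

# One-sided Hann-windowed periodogram. Power normalization is such that
# band powers integrate the PSD (power per Hz) over frequency.
hann_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- (x - mean(x)) * w
  sp <- fft(xw)
  half <- seq_len(floor(n / 2) + 1L)
  psd <- (Mod(sp[half])^2) / (fs * sum(w^2))
  scale2 <- rep(2, length(half))
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[length(half)] <- 1
  list(freq = (half - 1) * fs / n, psd = psd * scale2, df = fs / n)
}

band_power_from_pg <- function(pg, lo, hi, closed_hi = FALSE) {
  sel <- if (closed_hi) {
    pg$freq >= lo & pg$freq <= hi
  } else {
    pg$freq >= lo & pg$freq < hi
  }
  sum(pg$psd[sel]) * pg$df
}

band_features_from_pg <- function(pg, bands) {
  bp <- vapply(rownames(bands), function(b) {
    band_power_from_pg(pg, bands[b, "lo"], bands[b, "hi"],
                       closed_hi = (b == "gamma"))
  }, numeric(1))
  total <- band_power_from_pg(pg, min(bands), max(bands), closed_hi = TRUE)
  if (total <= 0) total <- .Machine$double.eps
  c(bp,
    bg_ratio = unname((bp["beta"] + bp["gamma"]) / total),
    dt_ratio = unname((bp["delta"] + bp["theta"]) / total))
}

#' Band powers and band-power ratios
#'
#' Integrates a Hann-windowed periodogram over the clinical bands (see
#' [eeg_bands()]). Total power is the integral over 0.5-50 Hz, so the two
#' ratio features (beta+gamma)/total and (delta+theta)/total lie in `[0, 1]`
#' and sum to at most 1.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param bands band-edge matrix, see [eeg_bands()].
#' @return named vector: delta, theta, alpha, beta, gamma, bg_ratio, dt_ratio.
#' @export
band_powers <- function(x, fs, bands = eeg_bands()) {
  check_series(x, 32L)
  band_features_from_pg(hann_periodogram(x, fs), bands)
}

median_frequency_from_pg <- function(pg, lo = 0.5, hi = 50) {
  sel <- which(pg$freq >= lo & pg$freq <= hi)
  p <- pg$psd[sel]
  tot <- sum(p)
  if (tot <= 0) return(pg$freq[sel[1]])
  # relative slack so a nominal 50/50 power split (whose lower line loses a
  # sliver of leakage below the band edge) resolves to the lower frequency
  pg$freq[sel[which(cumsum(p) >= 0.5 * tot * (1 - 1e-6))[1]]]
}

#' Median frequency
#'
#' The smallest frequency at which the cumulative periodogram power over
#' 0.5-50 Hz reaches 50% of the total in that range.
#'
#' @inheritParams band_powers
#' @return median frequency in Hz.
#' @export
median_frequency <- function(x, fs) {
  check_series(x, 32L)
  median_frequency_from_pg(hann_periodogram(x, fs))
}

## ---- complexity features --------------------------------------------------

#' Hurst exponent by rescaled range
#'
#' Classical R/S estimate: for dyadic window sizes m (powers of two from 8 up
#' to length/4) the series is split into blocks of m samples; each block's
#' rescaled range is the range of its cumulative mean-centred sums divided by
#' its standard deviation. The exponent is the slope of log mean(R/S) against
#' log m.
#'
#' @param x numeric series, length >= 64.
#' @return estimated Hurst exponent.
#' @export
hurst_exponent <- function(x) {
  check_series(x, 64L)
  check_nondegenerate(x)
  n <- length(x)
  sizes <- 2^(3:floor(log2(n / 4)))
  sizes <- sizes[sizes >= 8]
  if (length(sizes) < 2L) contract_error("series too short for R/S regression")
  log_rs <- log(rs_means_cpp(x, as.integer(sizes)))
  ok <- is.finite(log_rs)
  lm_x <- log(sizes[ok])
  lm_y <- log_rs[ok]
  sum((lm_x - mean(lm_x)) * (lm_y - mean(lm_y))) / sum((lm_x - mean(lm_x))^2)
}

#' Hjorth parameters
#'
#' Activity (variance), mobility (root variance ratio of the first difference
#' to the signal) and complexity (mobility of the first difference divided by
#' mobility of the signal).
#'
#' @param x numeric series, length >= 3.
#' @return list with `activity`, `mobility`, `complexity`.
#' @export
hjorth_params <- function(x) {
  check_series(x, 3L)
  check_nondegenerate(x)
  d1 <- diff(x)
  d2 <- diff(d1)
  v0 <- var(x); v1 <- var(d1); v2 <- var(d2)
  mob <- sqrt(v1 / v0)
  list(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

## ---- information-theoretic features ---------------------------------------

ami_bin_indices <- function(x, binning = c("equidistant", "equiprobable"), n_bins) {
  binning <- match.arg(binning)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) config_error("AMI needs at least 2 bins")
  if (binning == "equidistant") {
    edges <- seq(min(x), max(x), length.out = n_bins + 1L)
    findInterval(x, edges, all.inside = TRUE)
  } else {
    as.integer(ceiling(n_bins * rank(x, ties.method = "first") / length(x)))
  }
}

#' Auto-mutual information curve
#'
#' Plug-in mutual information (bits) between `x(t)` and `x(t + lag)` after
#' marginal binning, either equidistant (equal-width bins over the range) or
#' equiprobable (equal-count rank bins).
#'
#' @param x numeric series.
#' @param binning `"equidistant"` or `"equiprobable"`.
#' @param n_bins number of marginal bins (default 16).
#' @param lags integer vector of lags in samples (default 1:50; lag 0 is
#'   permitted and returns the marginal entropy).
#' @return named numeric vector of MI values, one per lag.
#' @export
auto_mutual_information <- function(x, binning = c("equidistant", "equiprobable"),
                                    n_bins = 16L, lags = 1:50) {
  binning <- match.arg(binning)
  check_series(x, max(lags) + 2L)
  check_nondegenerate(x)
  bins <- ami_bin_indices(x, binning, n_bins)
  out <- ami_curve_cpp(bins, as.integer(n_bins), as.integer(lags))
  names(out) <- paste0("lag", lags)
  out
}

#' First local minimum of an AMI curve
#'
#' The smallest lag that is a strict local minimum of the curve over lags
#' `1..max_lag`; if the curve has no interior strict minimum the largest lag
#' is returned.
#'
#' @param curve numeric AMI values at lags `1..length(curve)`.
#' @return integer lag.
#' @export
first_ami_minimum <- function(curve) {
  l <- length(curve)
  if (l < 3L) return(l)
  for (tau in 2:(l - 1L)) {
    if (curve[tau] < curve[tau - 1L] && curve[tau] < curve[tau + 1L]) {
      return(tau)
    }
  }
  l
}

#' Bicorrelation
#'
#' Third-order correlation `B(tau) = mean_t x(t) x(t+tau) x(t+2 tau)`,
#' averaged over the supplied lags. Assumes an (approximately) zero-mean,
#' unit-variance input, as produced by the preprocessing chain; for symmetric
#' linear processes the expectation is zero, so nonzero values indicate
#' quadratic phase coupling or asymmetry.
#'
#' @param x numeric series (zero mean, unit variance).
#' @param lags integer lags in samples (default 1:20).
#' @return mean bicorrelation over `lags`.
#' @export
bicorrelation <- function(x, lags = 1:20) {
  check_series(x, 2L * max(lags) + 10L)
  vals <- vapply(lags, function(tau) {
    n <- length(x) - 2L * tau
    mean(x[1:n] * x[(1 + tau):(n + tau)] * x[(1 + 2L * tau):(n + 2L * tau)])
  }, numeric(1))
  mean(vals)
}

## ---- autocorrelation features ----------------------------------------------

#' Lag-1 Spearman/Pearson autocorrelation and lag-2 partial autocorrelation
#'
#' The partial autocorrelation is taken at lag 2 (the first lag at which it
#' differs from the ordinary lag-1 autocorrelation), through the
#' Durbin-Levinson identity `phi_22 = (r2 - r1^2) / (1 - r1^2)` on the biased
#' autocorrelation estimates.
#'
#' @param x numeric series, length >= 30.
#' @return named vector `c(spearman, pearson, pacf2)`.
#' @export
autocorr_features <- function(x) {
  check_series(x, 30L)
  check_nondegenerate(x)
  n <- length(x)
  r <- stats::acf(x, lag.max = 2L, plot = FALSE, demean = TRUE)$acf[2:3]
  c(
    spearman = cor(x[-n], x[-1], method = "spearman"),
    pearson = cor(x[-n], x[-1]),
    pacf2 = (r[2] - r[1]^2) / (1 - r[1]^2)
  )
}

## ---- ordinal-pattern entropy -----------------------------------------------

# Order-3 ordinal pattern codes at a given lag, with ties (absolute pairwise
# difference below the threshold) mapped to dedicated tie patterns. Codes are
# built from the trichotomized signs of the three pairwise differences; the
# six strict orderings give six codes, tied triplets land on distinct extra
# codes.
ordinal_pattern_codes <- function(x, lag, tie_threshold) {
  n <- length(x) - 2L * lag
  if (n < 1L) contract_error("series too short for order-3 patterns at this lag")
  x1 <- x[1:n]
  x2 <- x[(1 + lag):(n + lag)]
  x3 <- x[(1 + 2L * lag):(n + 2L * lag)]
  tri <- function(d) {
    s <- sign(d)
    s[abs(d) <= tie_threshold] <- 0
    as.integer(s)
  }
  (tri(x2 - x1) + 1L) * 9L + (tri(x3 - x2) + 1L) * 3L + (tri(x3 - x1) + 1L) + 1L
}

pattern_entropy_bits <- function(codes) {
  p <- tabulate(codes, 27L)
  p <- p[p > 0] / length(codes)
  -sum(p * log2(p))
}

#' Composite permutation entropy index (CPEI)
#'
#' Order-3 ordinal-pattern entropy computed at lags 1 and 2. At each lag the
#' Shannon entropy of the pattern distribution (ties below `tie_threshold`
#' mapped to dedicated tie patterns) is normalized by `log2(6)`, the entropy
#' of the six equiprobable tie-free patterns; the index is the sum of the two
#' normalized entropies, so it ranges from 0 (deterministic monotone trend)
#' to about 2 (white noise).
#'
#' @param x numeric series.
#' @param tie_threshold absolute difference below which samples tie.
#' @return CPEI value.
#' @export
cpei <- function(x, tie_threshold = 1e-6) {
  check_series(x, 7L)
  sum(vapply(c(1L, 2L), function(lag) {
    pattern_entropy_bits(ordinal_pattern_codes(x, lag, tie_threshold)) / log2(6)
  }, numeric(1)))
}

## ---- epoch / trial aggregation ---------------------------------------------

channel_features <- function(x, fs, config, pg = NULL) {
  check_nondegenerate(x)
  if (is.null(pg)) pg <- hann_periodogram(x, fs)
  mom <- moment_features(x)
  bands <- band_features_from_pg(pg, config$bands)
  lags <- seq_len(config$ami_max_lag)
  ami_e <- ami_curve_cpp(ami_bin_indices(x, "equidistant", config$ami_bins),
                         config$ami_bins, lags)
  ami_q <- ami_curve_cpp(ami_bin_indices(x, "equiprobable", config$ami_bins),
                         config$ami_bins, lags)
  ac <- autocorr_features(x)
  c(
    f4 = unname(mom["variance"]),
    f5 = unname(mom["skewness"]),
    f6 = unname(mom["kurtosis"]),
    f7 = unname(bands["delta"]), f8 = unname(bands["theta"]),
    f9 = unname(bands["alpha"]), f10 = unname(bands["beta"]),
    f11 = unname(bands["gamma"]),
    f12 = unname(bands["bg_ratio"]), f13 = unname(bands["dt_ratio"]),
    f14 = hurst_exponent(x),
    f15 = hjorth_params(x)$complexity,
    f16 = ami_e[1],
    f17 = ami_q[1],
    f18 = first_ami_minimum(ami_e),
    f19 = first_ami_minimum(ami_q),
    f20 = bicorrelation(x, config$bicor_lags),
    f21 = median_frequency_from_pg(pg),
    f22 = unname(ac["spearman"]),
    f23 = unname(ac["pearson"]),
    f24 = unname(ac["pacf2"]),
    f25 = cpei(x, config$cpei_tie_threshold)
  )
}

#' Feature vector of one epoch
#'
#' Computes the 25-feature vector: f1-f3 once from the joint multichannel
#' MVAR(1) fit, f4-f25 per channel and then averaged arithmetically across
#' channels. Any degenerate (constant) channel raises a degenerate-channel
#' condition, which [trial_features()] uses to flag and drop the epoch.
#'
#' @param epoch channels x samples matrix (preprocessed).
#' @param fs sampling rate in Hz.
#' @param config a [feature_config()].
#' @return named numeric vector `f1..f25`.
#' @export
epoch_features <- function(epoch, fs, config = feature_config()) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  for (i in seq_len(nrow(epoch))) check_nondegenerate(epoch[i, ])
  model <- fit_mvar(epoch, config$mvar_order)
  eig <- mvar_eigen_features(model, config$eig_threshold)
  per_ch <- vapply(seq_len(nrow(epoch)), function(i) {
    channel_features(epoch[i, ], fs, config)
  }, numeric(22))
  out <- c(eig, rowMeans(per_ch))
  names(out) <- paste0("f", 1:25)
  if (any(!is.finite(out))) {
    degenerate_channel_error("non-finite feature value in epoch")
  }
  out
}

#' Feature vector of a trial
#'
#' Componentwise arithmetic mean of the epoch feature vectors. Epochs with a
#' degenerate channel are flagged, logged and excluded; a trial whose epochs
#' are all flagged raises a trial-dropped error.
#'
#' @param trial a trial from [segment()].
#' @param fs sampling rate in Hz.
#' @param config a [feature_config()].
#' @return named numeric vector `f1..f25`, with attribute `n_epochs_used`.
#' @export
trial_features <- function(trial, fs, config = feature_config()) {
  vecs <- lapply(trial$epochs, function(ep) {
    tryCatch(epoch_features(ep, fs, config),
             eegdloc_degenerate_channel = function(e) NULL)
  })
  dropped <- sum(vapply(vecs, is.null, logical(1)))
  if (dropped > 0) {
    message(sprintf("subject %s trial %d: %d of %d epochs flagged degenerate and dropped",
                    trial$subject_id, trial$trial_index, dropped, length(vecs)))
  }
  vecs <- vecs[!vapply(vecs, is.null, logical(1))]
  if (length(vecs) == 0L) {
    stop_eegdloc(sprintf("all epochs of subject %s trial %d flagged; trial dropped",
                         trial$subject_id, trial$trial_index),
                 "eegdloc_trial_dropped")
  }
  out <- Reduce(`+`, vecs) / length(vecs)
  attr(out, "n_epochs_used") <- length(vecs)
  out
}

#' Trial feature table for a set of recordings
#'
#' Preprocesses each recording, segments it, and computes one feature row per
#' trial.
#'
#' @param recordings list of `eeg_recording` objects.
#' @param labels character vector of class labels, one per recording
#'   (`"focal"`/`"diffuse"`), or NULL.
#' @param plan a [segmentation_plan()].
#' @param config a [feature_config()].
#' @param montage,filter passed to [preprocess_recording()].
#' @return data.frame with columns subject_id, trial_index, label, f1..f25.
#' @export
cohort_features <- function(recordings, labels = NULL,
                            plan = segmentation_plan(),
                            config = feature_config(),
                            montage = "auto", filter = TRUE) {
  rows <- list()
  for (k in seq_along(recordings)) {
    rec <- preprocess_recording(recordings[[k]], montage = montage, filter = filter)
    trials <- segment(rec, plan)
    for (tr in trials) {
      fv <- tryCatch(trial_features(tr, rec$fs, config),
                     eegdloc_trial_dropped = function(e) NULL)
      if (is.null(fv)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = tr$subject_id,
        trial_index = tr$trial_index,
        label = if (is.null(labels)) NA_character_ else labels[k],
        t(as.matrix(fv)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(subject_id = character(0), trial_index = integer(0),
                      label = character(0)))
  }
  do.call(rbind, rows)
}
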