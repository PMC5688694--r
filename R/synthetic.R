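# Synthetic 18-channel EEG cohorts. The generator targets the feature-level
# statistical structure the classifier consumes — not biophysical realism:
# each subject's signal is the sum of a stable order-1 MVAR process (joint
# damped dynamics, controls the eigenvalue features), band-shaped oscillatory
# components (controls the band-power features) and broadband white noise
# (controls the entropy/complexity features).

#' Class profile for the synthetic generator
#'
#' @param label class name, e.g. `"focal"` or `"diffuse"`.
#' @param mvar_spectral_radius target maximum eigenvalue modulus of the
#'   MVAR coupling matrix, in (0, 1).
#' @param band_weights named nonnegative weights (delta, theta, alpha, beta,
#'   gamma) for the oscillatory part; normalized to sum to 1.
#' @param complexity_level fraction in `[0, 1]` of signal standard deviation
#'   contributed by broadband white noise; raises entropy features.
#' @param channel_heterogeneity standard deviation of per-channel gain
#'   dispersion around 1.
#' @param subject_variability standard deviation of per-subject
#'   log-normal jitter applied to the profile parameters.
#' @param osc_fraction fraction of the non-noise power given to the
#'   oscillatory part (the rest drives the MVAR part); 0 yields a pure
#'   MVAR-plus-noise process.
#' @return object of class `class_profile`.
#' @export
class_profile <- function(label,
                          mvar_spectral_radius = 0.7,
                          band_weights = c(delta = 0.2, theta = 0.2, alpha = 0.2,
                                           beta = 0.2, gamma = 0.2),
                          complexity_level = 0.5,
                          channel_heterogeneity = 0.1,
                          subject_variability = 0.1,
                          osc_fraction = 0.5) {
  if (mvar_spectral_radius <= 0 || mvar_spectral_radius >= 1) {
    config_error("mvar_spectral_radius must lie in (0, 1) for a stable generator")
  }
  if (any(band_weights < 0) || sum(band_weights) <= 0) {
    config_error("band_weights must be nonnegative with positive sum")
  }
  if (complexity_level < 0 || complexity_level > 1) {
    config_error("complexity_level must lie in [0, 1]")
  }
  structure(
    list(label = label,
         mvar_spectral_radius = mvar_spectral_radius,
         band_weights = band_weights / sum(band_weights),
         complexity_level = complexity_level,
         channel_heterogeneity = channel_heterogeneity,
         subject_variability = subject_variability,
         osc_fraction = osc_fraction),
    class = "class_profile"
  )
}

#' Default focal-like and diffuse-like class profiles
#'
#' Encodes the qualitative contrast between the two dynamical classes:
#' focal-like records are broadband and high-complexity (higher entropy
#' features), diffuse-like records concentrate power in the slow delta/theta
#' bands, have low broadband complexity, slower joint dynamics, and larger
#' between-subject variability (greater feature spread).
#'
#' @return named list of two [class_profile()]s.
#' @export
default_profiles <- function() {
  list(
    focal = class_profile(
      "focal",
      mvar_spectral_radius = 0.55,
      band_weights = c(delta = 0.10, theta = 0.15, alpha = 0.30,
                       beta = 0.25, gamma = 0.20),
      complexity_level = 0.65,
      channel_heterogeneity = 0.10,
      subject_variability = 0.10,
      osc_fraction = 0.5
    ),
    diffuse = class_profile(
      "diffuse",
      mvar_spectral_radius = 0.85,
      band_weights = c(delta = 0.55, theta = 0.27, alpha = 0.10,
                       beta = 0.05, gamma = 0.03),
      complexity_level = 0.15,
      channel_heterogeneity = 0.10,
      subject_variability = 0.30,
      osc_fraction = 0.5
    )
  )
}

#' Cohort specification
#'
#' Defaults mirror the study scale: 21 focal-like and 19 diffuse-like
#' subjects, 250 Hz, 200 s records (one 200 s trial of forty 5 s epochs per
#' subject at the default segmentation).
#'
#' @param n_focal,n_diffuse subject counts per class.
#' @param duration_s record duration in seconds.
#' @param fs sampling rate (Hz).
#' @param profiles named list with elements `focal` and `diffuse`.
#' @param seed master integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_focal = 21L, n_diffuse = 19L, duration_s = 200,
                        fs = 250, profiles = default_profiles(), seed = 1L) {
  if (n_focal < 1L || n_diffuse < 1L) config_error("subject counts must be >= 1")
  if (duration_s < 1) config_error("duration_s must cover at least one second")
  structure(
    list(n_focal = as.integer(n_focal), n_diffuse = as.integer(n_diffuse),
         duration_s = duration_s, fs = fs, profiles = profiles,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Random stable coupling matrix scaled to an exact spectral radius.
random_coupling_matrix <- function(n_ch, radius) {
  a <- matrix(rnorm(n_ch * n_ch, sd = 1 / sqrt(n_ch)), n_ch, n_ch)
  rho <- max(Mod(eigen(a, only.values = TRUE)$values))
  a * (radius / rho)
}

simulate_mvar1 <- function(a, n_samples, burn_in = 500L) {
  n_ch <- nrow(a)
  x <- matrix(0, n_ch, n_samples + burn_in)
  noise <- matrix(rnorm(n_ch * (n_samples + burn_in)), n_ch)
  v <- numeric(n_ch)
  for (t in seq_len(n_samples + burn_in)) {
    v <- drop(a %*% v) + noise[, t]
    x[, t] <- v
  }
  x[, (burn_in + 1L):(burn_in + n_samples), drop = FALSE]
}

# Oscillatory part: per band and channel, a sinusoid at a random frequency
# inside the band with random phase and slow random amplitude modulation,
# with RMS proportional to sqrt(band weight).
oscillatory_part <- function(n_ch, n_samples, fs, band_weights, bands = eeg_bands()) {
  tt <- seq_len(n_samples) / fs
  out <- matrix(0, n_ch, n_samples)
  for (b in rownames(bands)) {
    wgt <- band_weights[[b]]
    if (wgt <= 0) next
    lo <- bands[b, "lo"]
    hi <- min(bands[b, "hi"], fs / 2 - 1)
    for (i in seq_len(n_ch)) {
      f0 <- runif(1, lo, hi)
      ph <- runif(1, 0, 2 * pi)
      # slow amplitude modulation so band power fluctuates across epochs
      am <- 1 + 0.3 * sin(2 * pi * runif(1, 0.01, 0.05) * tt + runif(1, 0, 2 * pi))
      out[i, ] <- out[i, ] + sqrt(wgt) * sqrt(2) * am * sin(2 * pi * f0 * tt + ph)
    }
  }
  out
}

#' Generate one synthetic subject
#'
#' Draws per-subject parameter jitter from the profile, then synthesizes an
#' 18-channel recording as a weighted sum of a stable MVAR(1) process, the
#' band-shaped oscillatory part and broadband white noise, each normalized to
#' unit RMS per channel before weighting, with per-channel gain dispersion on
#' top. Deterministic given `seed`.
#'
#' @param profile a [class_profile()].
#' @param duration_s record length in seconds.
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @param subject_id identifier.
#' @return an `eeg_recording` with 18 bipolar-named channels; `meta` holds the
#'   class label, the realized coupling matrix `A` and the jittered
#'   parameters.
#' @export
generate_subject <- function(profile, duration_s = 200, fs = 250, seed = 1L,
                             subject_id = "synthetic") {
  n_ch <- 18L
  n_samples <- as.integer(round(duration_s * fs))
  withr::with_seed(as.integer(seed), {
    jit <- function(v) v * exp(rnorm(1, 0, profile$subject_variability))
    radius <- min(jit(profile$mvar_spectral_radius), 0.995)
    complexity <- min(max(jit(profile$complexity_level), 0), 1)
    bw <- profile$band_weights * exp(rnorm(length(profile$band_weights),
                                           0, profile$subject_variability))
    bw <- bw / sum(bw)
    a <- random_coupling_matrix(n_ch, radius)
    unit_rms <- function(m) m / pmax(sqrt(rowMeans(m^2)), 1e-12)
    w_noise <- complexity
    w_osc <- (1 - complexity) * profile$osc_fraction
    w_mvar <- (1 - complexity) * (1 - profile$osc_fraction)
    x <- matrix(0, n_ch, n_samples)
    if (w_mvar > 0) x <- x + w_mvar * unit_rms(simulate_mvar1(a, n_samples))
    if (w_osc > 0) {
      x <- x + w_osc * unit_rms(oscillatory_part(n_ch, n_samples, fs, bw))
    }
    if (w_noise > 0) {
      x <- x + w_noise * unit_rms(matrix(rnorm(n_ch * n_samples), n_ch))
    }
    gains <- pmax(1 + rnorm(n_ch, 0, profile$channel_heterogeneity), 0.2)
    x <- x * gains
    new_recording(
      x, rownames(default_bipolar_montage()), fs, subject_id,
      meta = list(label = profile$label, A = a, seed = seed,
                  params = list(mvar_spectral_radius = radius,
                                complexity_level = complexity,
                                band_weights = bw))
    )
  })
}

#' Generate a labelled synthetic cohort
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' the whole cohort is reproducible bitwise.
#'
#' @param spec a [cohort_spec()].
#' @return list with `recordings` (list of `eeg_recording`), `labels`
#'   (character vector) and `manifest` (data.frame: subject_id, label, seed).
#' @export
generate_cohort <- function(spec) {
  n <- spec$n_focal + spec$n_diffuse
  seeds <- derive_seeds(spec$seed, n)
  labels <- c(rep("focal", spec$n_focal), rep("diffuse", spec$n_diffuse))
  ids <- sprintf("S%02d", seq_len(n))
  recordings <- lapply(seq_len(n), function(i) {
    generate_subject(spec$profiles[[labels[i]]], spec$duration_s, spec$fs,
                     seed = seeds[i], subject_id = ids[i])
  })
  list(
    recordings = recordings,
    labels = labels,
    manifest = data.frame(subject_id = ids, label = labels, seed = seeds,
                          stringsAsFactors = FALSE)
  )
}
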