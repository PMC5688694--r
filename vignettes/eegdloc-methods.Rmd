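---
title: "Methods: quantitative EEG discrimination of focal and diffuse DLOC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative EEG discrimination of focal and diffuse DLOC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modelling stance

A depressed level of consciousness (DLOC) can follow a focal lesion that
disrupts arousal circuitry, or a diffuse process that degrades cortical
function globally. `eegdloc` implements a classifier for this dichotomy built
purely on the *temporal* dynamics of the scalp EEG: every feature is computed
channel by channel (or jointly across channels in time, for the
autoregressive features) and no spatial contrast — hemispheric asymmetry,
inter-regional coherence, topography — enters the model. That is a deliberate
restriction: it asks how much etiological signal lives in the time series
alone, and it keeps the method applicable to low-density clinical montages.

The analysis unit is the **trial**: a 200 s stretch of artifact-free signal,
split into forty 5 s **epochs**. Features are computed per epoch and averaged
over the trial's epochs, so each trial yields one 25-dimensional vector.
Multiple trials per subject give an empirical per-subject probability of each
class, but they are never split across the train/test boundary: all
cross-validation and holdout structure in this package operates on
**subjects**, and a runtime leakage guard aborts any evaluation where a
subject id appears on both sides. With short recordings this costs
statistical efficiency, which we accept for unbiased error estimates.

## Preprocessing

Order of operations: downsample, montage, normalize, filter, segment.

* **Downsampling.** 500 Hz input is decimated by 2 with an anti-aliasing
  lowpass (`signal::decimate`); naive sample-dropping would alias 125–250 Hz
  content into the analysis band. 250 Hz input passes through.
* **Montage.** The 18-pair longitudinal bipolar derivation over 10–20
  electrodes (FP1-F7 … P8-O2). Bipolar channels suppress the common reference
  and common-mode artifact.
* **Artifact handling.** The package consumes externally supplied artifact
  intervals (half-open `[start_s, end_s)`, 0-based); it performs no
  automatic detection. Intervals are canonicalized (sorted, merged, clipped);
  analysis uses the complementary artifact-free spans only, and epochs never
  straddle a span boundary.
* **Normalization.** Each channel is z-scored using statistics computed over
  the retained (artifact-free) samples only — an artifact inside the record
  must not distort the scaling of the clean segments. A channel with zero
  variance over retained samples raises a degenerate-channel error rather
  than propagating NaNs.
* **Filtering.** 10th-order Chebyshev type I lowpass, 50 Hz cutoff, 0.5 dB
  passband ripple (a conventional value; it affects only passband flatness),
  applied forward–backward. Zero-phase filtering avoids group delay that
  would misalign epochs; it doubles the effective stopband attenuation.
  Because a type I design has ripple at DC and the forward–backward pass has
  edge transients, the filter operates on the demeaned signal and the channel
  mean is restored exactly afterwards, so filtering never shifts a channel
  mean. For z-scored channels this only pins the mean at 0.
* **Segmentation.** Epochs tile each artifact-free span from its start;
  a trailing partial epoch in a span is discarded, and trailing epochs that
  do not fill a whole trial are discarded (and logged). The sentinel
  `n_epochs_per_trial = "all"` pools every complete epoch into one trial.

## The 25 features

Features f1–f3 come from a joint multichannel autoregressive model; f4–f25
are computed per bipolar channel and **averaged over the 18 channels**.
Averaging (rather than concatenating) keeps the vector 25-dimensional and is
the natural reduction when no spatial information is wanted.

* **f1–f3, MVAR eigenvalues.** An order-1 multivariate autoregressive model
  `x(t) = A x(t−1) + w(t)` is fitted by least squares on each epoch jointly
  over the 18 channels. The eigenvalue moduli of `A` measure the damping of
  the joint dynamics: f1 = max modulus, f2 = min modulus, f3 = number of
  moduli strictly above 0.95 (slow, weakly damped modes; severely depressed
  cortical dynamics concentrate power at low frequencies, which appears here
  as near-unit-modulus modes). Because each channel is z-scored, `A` is
  determined up to a diagonal similarity, which leaves its eigenvalues
  invariant — the features are insensitive to per-channel gain.
* **f4–f6, moments.** Sample variance (n−1), and skewness/kurtosis as
  standardized population central moments; kurtosis is **non-excess**
  (Gaussian = 3).
* **f7–f13, band powers.** One Hann-windowed periodogram per epoch (epochs as
  short as 1 s preclude multi-segment averaging), integrated over the
  clinical bands delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30 and gamma
  30–50 Hz (gamma capped at the filter cutoff). Total power is the 0.5–50 Hz
  integral, so f12 = (beta+gamma)/total and f13 = (delta+theta)/total lie in
  [0, 1] and the five band powers sum to the total.
* **f14, Hurst exponent.** Rescaled-range (R/S) estimate with dyadic windows
  from 8 samples up to length/4: the slope of log mean(R/S) against log
  window size. 0.5 for uncorrelated noise, approaching 1 for strongly
  persistent (integrated) signals.
* **f15, Hjorth complexity.** Of the three Hjorth parameters, activity
  duplicates f4 and mobility is strongly tied to the spectral features, so
  the feature slot carries complexity; all three are returned by
  `hjorth_params()` for inspection.
* **f16–f19, auto-mutual information.** Plug-in mutual information between
  the signal and its lagged copy after marginal binning — equidistant
  (equal-width) and equiprobable (rank) binning, 16 bins, lags 1–50 samples
  (0.2 s at 250 Hz). f16/f17 are the lag-1 values; f18/f19 are the first
  strict local minima of the two curves (the classical embedding-lag
  heuristic), with the maximum lag returned when no interior minimum exists.
* **f20, bicorrelation.** The third-order moment
  `B(τ) = mean_t x(t)·x(t+τ)·x(t+2τ)` averaged over τ = 1…20 samples. It
  vanishes in expectation for symmetric linear processes, so it indexes
  quadratic phase coupling and waveform asymmetry.
* **f21, median frequency.** Smallest frequency at which cumulative
  periodogram power over 0.5–50 Hz reaches 50% of the total. The crossing
  test carries a 1e-6 relative slack so that a nominal 50/50 split between
  two lines (where the lower line loses a sliver of leakage below the band
  edge) resolves to the lower frequency.
* **f22–f24, autocorrelations.** Spearman and Pearson correlations of
  `(x(t), x(t+1))`, and the partial autocorrelation at **lag 2** via the
  Durbin–Levinson identity `(r2 − r1²)/(1 − r1²)`. Lag 2 is used because the
  lag-1 partial autocorrelation is identically the Pearson lag-1
  autocorrelation and would duplicate f23.
* **f25, CPEI.** Order-3 ordinal patterns extracted at lags 1 and 2; the
  three pairwise comparisons of each triplet are trichotomized with a tie
  threshold of 1e-6 (on normalized data ties arise essentially only from
  clipping or quantization), ties landing on dedicated patterns. The Shannon
  entropy of each lag's pattern distribution is normalized by log2(6) — the
  entropy of the six equiprobable tie-free orderings — and the two normalized
  entropies are summed. A monotone trend scores 0; white noise scores ≈ 2.
  For heavily quantized signals the tie patterns can push a per-lag value
  slightly above 1; the index remains well defined.

An epoch containing a degenerate (constant) channel is flagged, logged and
excluded from the trial average; a trial with no usable epoch is dropped with
an error. Every feature is checked against an independently coded brute-force
implementation of its definition in the test suite.

## Classification

Within each training set, in order:

1. **Standardize** the 25 features by training mean/sd. A feature that is
   constant across training trials (typically f3 when no epoch produces an
   eigenvalue above 0.95) is dropped from the model with a message, since it
   cannot be standardized and carries no information.
2. **PCA** of the standardized features; the top K = 20 components are
   retained (capped at the matrix rank). Component signs are fixed so the
   largest-magnitude loading is positive, making results deterministic.
   On the synthetic cohorts the 20 components retain well above 98% of the
   variance. In `raw_features` mode this rotation is skipped.
3. **Importance ranking.** Each component alone is scored by its
   cross-validated ROC separability 2·|AUC − ½|, averaged over 10
   subject-level folds resampled 50 times. Folds whose held-out trials are
   single-class contribute nothing; should *no* fold contain both classes
   (only possible for degenerately small cohorts) the whole-sample AUC is
   used, with a message. Scores lie in [0, 1]; 1 means the component alone
   separates the classes perfectly on every held-out fold.
4. **Linear SVM** (cost 1.0 by default, exposed in config) on the 6 most
   important components (10 most important features in raw mode). The
   trained machine is reduced to its explicit affine decision function
   `d(x) = x·w + b`, oriented so positive means focal; a decision value of
   exactly 0 is classified focal. This keeps the decision rule serializable
   as plain text and independent of the SVM library at prediction time.

Two validation paradigms mirror the two ways the method is meant to be
judged. **Paradigm 1**: 500 repetitions (the package default; the test suite
and acceptance script use 100) of a random subject-level 2/3–1/3 split, the whole pipeline
refitted per repetition, metrics averaged. Splits are unstratified; a split
leaving a single class on either side is redrawn so the repetition count
stays fixed. **Paradigm 2**: a one-time dedicated holdout (default: the first
third of subjects, rounded down) with no resampling.

## Evaluation

*Soft accuracy* is the fraction of correctly labelled trials; *hard accuracy*
labels each subject by the majority of its trial votes and scores subjects.
An exact vote tie is resolved by the sign of the subject's mean SVM decision
value (non-negative → focal). Sensitivity and specificity take focal as the
positive class; if a class is absent from the truth the metric is returned as
NA with a warning, never as a silent zero. Every report asserts the identity
`hard = (sensitivity·n_focal + specificity·n_diffuse)/n` at construction.

Per-component group differences are tested with **Welch** two-sample t-tests
at a nominal 0.05 level without multiplicity correction: principal components
are mutually uncorrelated by construction (asserted in the tests), and the
two classes are not assumed to share a variance — the diffuse class is
expressly modelled as more heterogeneous.

## The synthetic cohort generator

No public DLOC EEG corpus exists, so the package ships a generator whose
**defaults are the study conditions** used throughout the tests: 21
focal-like and 19 diffuse-like subjects, 250 Hz, 200 s per record (one
default trial per subject). Each subject's 18-channel signal is the sum of
three unit-RMS parts with class-controlled weights:

* a stable order-1 MVAR process whose random coupling matrix is scaled to a
  target spectral radius (drives f1–f3),
* band-shaped oscillatory components — per band and channel a sinusoid at a
  random in-band frequency with random phase and slow amplitude modulation,
  weighted by the profile's band weights (drives f7–f13, f21),
* broadband white noise at the profile's `complexity_level` (drives the
  entropy/complexity features f14–f19, f25).

Per-subject log-normal jitter (`subject_variability`) and per-channel gain
dispersion (`channel_heterogeneity`) sit on top. The default **focal-like**
profile is broadband and high-complexity (radius 0.55, complexity 0.65, band
weights tilted to alpha/beta/gamma); the default **diffuse-like** profile is
slow and regular (radius 0.85, complexity 0.15, delta/theta-dominant) with
three times the subject variability, reproducing the directional contrast the
classifier targets: higher delta/theta ratio and lower entropy in diffuse-like
records, and a visibly larger diffuse spread in PC space. Class contrast is
encoded only through these interpretable knobs — never as an additive offset
on features — so recovery tests exercise the real feature pathways. The
effect sizes are free design parameters of the generator, not estimates of
the clinical contrast: passing the separability test demonstrates that the
pipeline recovers structure of this kind, not that clinical data carry this
much signal. Nor does the generator emulate nonstationarity, real artifact
morphology, volume conduction, electrode failures or medication effects.

## Numerical choices and problem sizes

* Epoch/trial defaults 5 s / 40 epochs; the grid utilities cover 1/5/20 s ×
  10/20/40/100/all epochs per trial.
* AMI: 16 bins, max lag 50 samples; bicorrelation lags 1–20; CPEI tie
  threshold 1e-6; all exposed in `feature_config()`.
* Degenerate inputs: constant channels, single-class folds, constant feature
  columns, infeasible grid cells and missing recordings each have a defined,
  logged behaviour (flag/drop/NA) rather than an unchecked failure.
* The test suite and the acceptance script run the repeated-split paradigm at
  100 repetitions on 40-subject, 200 s cohorts and fit spectral-radius
  recovery on single 200 s records — sizes chosen so the full pipeline is
  exercised end-to-end in minutes on one core while keeping the Monte-Carlo
  error of the reported averages near the percent level.
* Determinism: every stochastic step (generator, fold resampling, repetition
  splits) draws from seeds derived from one master seed; identical seeds give
  bitwise-identical cohorts, rankings and reports.

## Known limitations

* The headline clinical question — how well these features separate focal
  from diffuse DLOC in patients — cannot be answered by this package alone;
  the synthetic cohorts validate the machinery, not the clinical effect size.
* Hard accuracy on even trial counts depends on the documented tie rule.
* The importance ranking is noisy when subject-level folds contain very few
  trials; at the default cohort scale (two to three subjects per held-out
  fold) it is stable, but tiny cohorts should lower `n_folds`.
* R/S Hurst estimation and plug-in mutual information both carry known
  small-sample biases; they are used as discriminative features, not as
  unbiased estimates of their population quantities.
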