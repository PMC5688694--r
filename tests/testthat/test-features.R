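# The 25-feature suite: worked examples, statistical calibration and
# metamorphic invariants. (Equivalence of every feature with the brute-force
# oracles on short inputs lives in test-acceptance.R.)

fs <- 250

test_that("moment features follow the documented conventions", {
  m <- moment_features(c(1, 2, 3, 4))
  expect_equal(unname(m["variance"]), 5 / 3, tolerance = 1e-12) # sample variance
  expect_equal(unname(m["skewness"]), 0, tolerance = 1e-12)

  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(unname(moment_features(sym)["skewness"]), 0, tolerance = 1e-12)

  set.seed(1)
  g <- rnorm(2e5)
  expect_equal(unname(moment_features(g)["kurtosis"]), 3, tolerance = 0.1)
  expect_error(moment_features(rep(2, 10)), class = "eegdloc_degenerate_channel")
})

test_that("band powers concentrate where the signal lives", {
  tt <- (0:(5 * fs - 1)) / fs
  alpha <- band_powers(sin(2 * pi * 10 * tt), fs)
  expect_gt(alpha["alpha"] / sum(alpha[1:5]), 0.95)
  expect_lt(alpha["delta"] / sum(alpha[1:5]), 0.02)

  slow <- band_powers(sin(2 * pi * 2 * tt), fs)
  expect_gt(slow["dt_ratio"], 0.95)
  expect_lt(slow["bg_ratio"], 0.02)

  both <- band_powers(sin(2 * pi * 2 * tt) + sin(2 * pi * 40 * tt), fs)
  expect_equal(unname(both["bg_ratio"]), 0.5, tolerance = 0.05)
  expect_equal(unname(both["dt_ratio"]), 0.5, tolerance = 0.05)
})

test_that("band ratios are disjoint fractions of total power", {
  set.seed(2)
  for (i in 1:20) {
    bp <- band_powers(rnorm(fs * runif(1, 1, 4)), fs)
    expect_true(all(bp[1:5] >= 0))
    expect_gte(bp["bg_ratio"], 0)
    expect_gte(bp["dt_ratio"], 0)
    expect_lte(bp["bg_ratio"] + bp["dt_ratio"], 1 + 1e-9)
  }
})

test_that("median frequency follows the cumulative-power definition", {
  tt <- (0:(8 * fs - 1)) / fs
  expect_equal(median_frequency(sin(2 * pi * 10 * tt), fs), 10, tolerance = fs / (8 * fs))
  two <- median_frequency(sin(2 * pi * 5 * tt) + sin(2 * pi * 15 * tt), fs)
  expect_lt(abs(two - 5), 0.3) # smallest frequency reaching 50%
  set.seed(3)
  flat <- lowpass_filter(zscore_channels(new_recording(
    matrix(rnorm(fs * 60), 1), "bb", fs
  )))
  expect_lt(abs(median_frequency(flat$data[1, ], fs) - 25), 2)
})

test_that("Hurst exponent separates white noise from integrated noise", {
  set.seed(4)
  w <- rnorm(1e4)
  expect_lt(abs(hurst_exponent(w) - 0.5), 0.1)
  expect_lt(abs(hurst_exponent(cumsum(w)) - 1.0), 0.15)
  expect_error(hurst_exponent(rep(1, 1000)), class = "eegdloc_degenerate_channel")
})

test_that("Hjorth parameters have their closed-form sinusoid values", {
  tt <- (0:(10 * fs - 1)) / fs
  for (f0 in c(2, 10, 25)) {
    h <- hjorth_params(sin(2 * pi * f0 * tt))
    expect_equal(h$complexity, 1, tolerance = 0.01)
    expect_equal(h$mobility, 2 * sin(pi * f0 / fs), tolerance = 1e-3)
  }
  set.seed(5)
  expect_gt(hjorth_params(rnorm(5000))$complexity, 1)
})

test_that("auto-mutual information is exact at lag 0 and small for iid noise", {
  set.seed(6)
  x <- rnorm(64 * 4)
  # equiprobable bins with n divisible by n_bins: MI(lag 0) = log2(n_bins)
  mi0 <- auto_mutual_information(x, "equiprobable", n_bins = 4, lags = 0)
  expect_equal(unname(mi0), log2(4), tolerance = 1e-12)

  y <- rnorm(2e4)
  for (binning in c("equidistant", "equiprobable")) {
    mi <- auto_mutual_information(y, binning, n_bins = 16, lags = c(1, 5, 20))
    expect_true(all(mi < 0.05))
  }
  expect_error(auto_mutual_information(y, "equidistant", n_bins = 1),
               class = "eegdloc_config_error")
})

test_that("the first AMI minimum of a sinusoid sits near the quarter period", {
  period <- 50 # 5 Hz at 250 Hz
  tt <- 0:(fs * 20 - 1)
  x <- sin(2 * pi * tt / period)
  curve <- auto_mutual_information(x, "equiprobable", n_bins = 16, lags = 1:50)
  expect_equal(first_ami_minimum(curve), period / 4, tolerance = 3)
  # monotone curve with no interior minimum returns the largest lag
  expect_equal(first_ami_minimum(c(5, 4, 3, 2, 1)), 5)
})

test_that("bicorrelation vanishes for symmetric noise and detects phase coupling", {
  set.seed(7)
  n <- 2e4
  reps <- vapply(1:40, function(i) bicorrelation(rnorm(n)), numeric(1))
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)) + 1e-3)

  # quadratically phase-coupled tones vs phase-randomized surrogates
  tt <- (0:(n - 1)) / fs
  f1 <- 6; f2 <- 11
  x <- cos(2 * pi * f1 * tt) + cos(2 * pi * f2 * tt) + cos(2 * pi * (f1 + f2) * tt)
  x <- (x - mean(x)) / sd(x)
  observed <- abs(bicorrelation(x))
  surr <- vapply(1:39, function(i) {
    set.seed(100 + i)
    sp <- fft(x)
    half <- 2:(n / 2)
    ph <- runif(length(half), 0, 2 * pi)
    sp[half] <- Mod(sp[half]) * exp(1i * ph)
    sp[n + 2 - half] <- Conj(sp[half])
    xs <- Re(fft(sp, inverse = TRUE)) / n
    abs(bicorrelation((xs - mean(xs)) / sd(xs)))
  }, numeric(1))
  expect_gt(observed, quantile(surr, 0.95))
})

test_that("autocorrelation features match their generating processes", {
  x <- make_ar1(5e4, phi = 0.9, seed = 8)
  ac <- autocorr_features(x)
  expect_equal(unname(ac["pearson"]), 0.9, tolerance = 0.02)
  expect_equal(unname(ac["pacf2"]), 0, tolerance = 0.03) # AR(1) PACF dies at lag 2
  expect_equal(unname(autocorr_features(sort(rnorm(100)))["spearman"]), 1)
  # lag-2 partial autocorrelation agrees with the standard pacf estimator
  expect_equal(unname(autocorr_features(x)["pacf2"]),
               stats::pacf(x, lag.max = 2, plot = FALSE)$acf[2],
               tolerance = 1e-10)
})

test_that("CPEI spans its degenerate and maximal regimes", {
  expect_equal(cpei(seq_len(300)), 0, tolerance = 1e-12) # one pattern per lag
  set.seed(9)
  noise <- rnorm(5e4)
  per_lag_max <- cpei(noise) / 2
  expect_gt(per_lag_max, 0.95) # six equiprobable tie-free patterns
  alt <- rep(c(0, 1), 200)
  # lag 1 of a period-2 series uses exactly two patterns (1 bit / log2(6));
  # at lag 2 every triplet is fully tied, contributing zero entropy
  expect_equal(cpei(alt), 1 / log2(6), tolerance = 1e-12)
})

test_that("scaling leaves standardized/rank/entropy features unchanged", {
  set.seed(10)
  x <- as.vector(arima.sim(list(ar = 0.6), 2000))
  cfg <- feature_config()
  base <- epoch_features(matrix(x, 1), fs, cfg)
  scaled <- epoch_features(matrix(3.7 * x, 1), fs, cfg)
  invariant <- paste0("f", c(5, 6, 14, 15, 16, 17, 18, 19, 21, 22, 23, 24, 25))
  expect_equal(scaled[invariant], base[invariant], tolerance = 1e-8)
  expect_equal(unname(scaled["f4"]), unname(3.7^2 * base["f4"]), tolerance = 1e-8)
})

test_that("time reversal leaves spectral and moment features unchanged", {
  set.seed(11)
  x <- as.vector(arima.sim(list(ar = c(0.5, 0.2)), 2000))
  cfg <- feature_config()
  fwd <- epoch_features(matrix(x, 1), fs, cfg)
  rev_ <- epoch_features(matrix(rev(x), 1), fs, cfg)
  sym <- paste0("f", c(4:13, 21, 23))
  expect_equal(rev_[sym], fwd[sym], tolerance = 1e-8)
})

test_that("epoch features aggregate channels and respect type invariants", {
  tt <- (0:(5 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * tt) + 0.1 * sin(2 * pi * 3 * tt + 1)
  set.seed(12)
  ep <- matrix(rep(x, 18), nrow = 18, byrow = TRUE)
  ep <- ep + matrix(rnorm(length(ep), sd = 1e-6), nrow = 18) # break exact collinearity
  v <- epoch_features(ep, fs)
  single <- epoch_features(matrix(x, 1), fs)
  expect_equal(unname(v["f4"]), unname(single["f4"]), tolerance = 1e-3)
  expect_equal(unname(v["f21"]), unname(single["f21"]), tolerance = 1e-3)

  wn <- matrix(rnorm(18 * 5 * fs), 18)
  vw <- epoch_features(wn, fs)
  expect_equal(unname(vw["f3"]), 0)
  expect_true(all(is.finite(vw)))
  expect_gte(vw["f1"], vw["f2"])
  expect_gte(vw["f2"], 0)
  expect_true(vw["f12"] >= 0 && vw["f12"] <= 1)
  expect_true(vw["f13"] >= 0 && vw["f13"] <= 1)
  expect_true(vw["f21"] > 0 && vw["f21"] <= fs / 2)
  expect_true(all(abs(vw[c("f22", "f23", "f24")]) <= 1))
  expect_gte(vw["f25"], 0)
})

test_that("trial features average epochs and drop degenerate ones", {
  set.seed(13)
  e1 <- matrix(rnorm(2 * 1250), 2)
  e2 <- matrix(rnorm(2 * 1250, sd = 2), 2)
  trial <- list(subject_id = "S", trial_index = 1, epochs = list(e1, e2))
  tv <- trial_features(trial, fs)
  v1 <- epoch_features(e1, fs)
  v2 <- epoch_features(e2, fs)
  expect_equal(as.numeric(tv), as.numeric((v1 + v2) / 2), tolerance = 1e-12)

  single <- trial_features(list(subject_id = "S", trial_index = 1,
                                epochs = list(e1)), fs)
  expect_equal(as.numeric(single), as.numeric(v1))

  flat <- matrix(0, 2, 1250)
  mixed <- list(subject_id = "S", trial_index = 1, epochs = list(e1, flat))
  expect_message(tm <- trial_features(mixed, fs), "flagged")
  expect_equal(attr(tm, "n_epochs_used"), 1)
  expect_error(
    suppressMessages(trial_features(list(subject_id = "S", trial_index = 1,
                                         epochs = list(flat)), fs)),
    class = "eegdloc_trial_dropped"
  )
})

test_that("long-epoch MVAR feature estimates converge to the generator radius", {
  for (rho in c(0.5, 0.9)) {
    rec <- generate_subject(
      class_profile("test", mvar_spectral_radius = rho, complexity_level = 0,
                    osc_fraction = 0, subject_variability = 0),
      duration_s = 100, fs = fs, seed = 42
    )
    z <- zscore_channels(rec)
    f <- mvar_eigen_features(fit_mvar(z$data), 0.95)
    expect_lt(abs(unname(f["f1"]) - rho), 0.03)
    expect_equal(unname(f["f3"]),
                 sum(Mod(eigen(rec$meta$A)$values) > 0.95))
  }
})
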