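# Programmatic fixtures shared across test files.

make_recording <- function(n_ch = 2, seconds = 10, fs = 250, seed = 1,
                           labels = NULL, artifacts = NULL) {
  set.seed(seed)
  data <- matrix(rnorm(n_ch * seconds * fs), nrow = n_ch)
  if (is.null(labels)) labels <- paste0("CH", seq_len(n_ch))
  new_recording(data, labels, fs, subject_id = paste0("T", seed),
                artifact_intervals = artifacts)
}

# Referential 19-electrode recording covering the standard montage.
electrodes_1020 <- function() {
  unique(as.vector(default_bipolar_montage()))
}

make_referential_recording <- function(seconds = 4, fs = 250, seed = 1) {
  labs <- electrodes_1020()
  set.seed(seed)
  new_recording(matrix(rnorm(length(labs) * seconds * fs), nrow = length(labs)),
                labs, fs, subject_id = "REF")
}

# Stationary AR(1) series with coefficient phi.
make_ar1 <- function(n, phi, seed = 1, burn = 200) {
  set.seed(seed)
  e <- rnorm(n + burn)
  x <- numeric(n + burn)
  for (t in 2:(n + burn)) x[t] <- phi * x[t - 1] + e[t]
  x[(burn + 1):(burn + n)]
}

# Small labelled feature table with a multivariate class separation (shift on
# f1..f6, so the class contrast concentrates in a leading PC after
# standardization) plus noise features; several trials per subject.
make_feature_table <- function(n_per_class = 8, trials = 3, n_feat = 25,
                               sep = 3, seed = 1) {
  set.seed(seed)
  rows <- list()
  sid <- 0
  for (lab in c("focal", "diffuse")) {
    for (s in seq_len(n_per_class)) {
      sid <- sid + 1
      shift <- if (lab == "focal") sep else 0
      for (tr in seq_len(trials)) {
        f <- rnorm(n_feat)
        f[1:6] <- f[1:6] + shift
        row <- as.data.frame(as.list(stats::setNames(f, paste0("f", seq_len(n_feat)))))
        rows[[length(rows) + 1]] <- cbind(
          data.frame(subject_id = sprintf("S%02d", sid), trial_index = tr,
                     label = lab, stringsAsFactors = FALSE),
          row
        )
      }
    }
  }
  do.call(rbind, rows)
}

# Per-trial prediction frame for evaluation tests.
make_predictions <- function(subject_id, label, predicted, decision_value = NULL) {
  if (is.null(decision_value)) {
    decision_value <- ifelse(predicted == "focal", 1, -1)
  }
  data.frame(subject_id = subject_id, trial_index = seq_along(subject_id),
             label = label, predicted = predicted,
             decision_value = decision_value, stringsAsFactors = FALSE)
}
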