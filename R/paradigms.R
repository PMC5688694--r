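# The two validation paradigms. Both operate on a per-trial feature table and
# enforce subject-level train/test independence: every subject's trials land
# entirely in the training set or entirely in the testing set.

#' Repeated random-split validation (paradigm 1)
#'
#' Each repetition draws a random subject-level split (`train_fraction` of
#' subjects for training), refits the entire pipeline (standardize, PCA,
#' importance ranking, selection, SVM) on training subjects only, and
#' evaluates on the held-out subjects. Splits that leave a single class in
#' either half are redrawn, keeping the repetition count fixed. Metrics are
#' averaged over repetitions; everything is deterministic given `seed`.
#'
#' @param features_df trial feature table from [cohort_features()] with a
#'   `label` column.
#' @param n_repetitions number of random splits (default 500).
#' @param train_fraction fraction of subjects assigned to training
#'   (default 2/3).
#' @param seed master integer seed.
#' @param mode,K,n_selected,n_folds,n_resamples,cost passed to
#'   [build_classifier()].
#' @return object of class `paradigm1_result`: averaged `hard_accuracy`,
#'   `soft_accuracy`, `sensitivity`, `specificity`; `per_repetition`
#'   data.frame; `n_redraws`; the last repetition's importance ranking and PC
#'   model for inspection.
#' @export
run_paradigm1 <- function(features_df, n_repetitions = 500L,
                          train_fraction = 2 / 3, seed = 1L,
                          mode = "pca", K = 20L, n_selected = NULL,
                          n_folds = 10L, n_resamples = 50L, cost = 1) {
  subjects <- unique(features_df$subject_id)
  subj_label <- vapply(subjects, function(s) {
    features_df$label[features_df$subject_id == s][1]
  }, character(1))
  if (sum(subj_label == "focal") < 3L || sum(subj_label == "diffuse") < 3L) {
    contract_error("paradigm 1 needs >= 3 subjects per class")
  }
  n_train <- max(2L, floor(train_fraction * length(subjects)))
  if (n_train >= length(subjects)) contract_error("train_fraction leaves no test subjects")
  seeds <- derive_seeds(seed, n_repetitions)
  rows <- vector("list", n_repetitions)
  n_redraws <- 0L
  last_clf <- NULL
  for (rep_i in seq_len(n_repetitions)) {
    draw_seed <- seeds[rep_i]
    repeat {
      train_subj <- withr::with_seed(draw_seed, sample(subjects, n_train))
      ok <- length(unique(subj_label[subjects %in% train_subj])) == 2L &&
        length(unique(subj_label[!(subjects %in% train_subj)])) == 2L
      if (ok) break
      n_redraws <- n_redraws + 1L
      draw_seed <- (draw_seed + 777L) %% .Machine$integer.max + 1L
    }
    train_df <- features_df[features_df$subject_id %in% train_subj, , drop = FALSE]
    test_df <- features_df[!(features_df$subject_id %in% train_subj), , drop = FALSE]
    clf <- build_classifier(train_df, mode = mode, K = K, n_selected = n_selected,
                            n_folds = n_folds, n_resamples = n_resamples,
                            cost = cost, seed = seeds[rep_i])
    rep_report <- evaluation_report(predict_trials(clf, test_df))
    rows[[rep_i]] <- data.frame(
      repetition = rep_i,
      hard_accuracy = rep_report$hard_accuracy,
      soft_accuracy = rep_report$soft_accuracy,
      sensitivity = rep_report$sensitivity,
      specificity = rep_report$specificity
    )
    last_clf <- clf
  }
  per_rep <- do.call(rbind, rows)
  if (n_redraws > 0L) {
    message(sprintf("paradigm 1: %d degenerate single-class split(s) redrawn", n_redraws))
  }
  structure(
    list(
      hard_accuracy = mean(per_rep$hard_accuracy),
      soft_accuracy = mean(per_rep$soft_accuracy),
      sensitivity = mean(per_rep$sensitivity, na.rm = TRUE),
      specificity = mean(per_rep$specificity, na.rm = TRUE),
      per_repetition = per_rep,
      n_repetitions = n_repetitions,
      n_redraws = n_redraws,
      last_classifier = last_clf
    ),
    class = "paradigm1_result"
  )
}

#' @export
print.paradigm1_result <- function(x, ...) {
  cat(sprintf(
    "<paradigm1_result> %d repetitions: hard %.3f | soft %.3f | sens %.3f | spec %.3f\n",
    x$n_repetitions, x$hard_accuracy, x$soft_accuracy, x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' Dedicated-holdout validation (paradigm 2)
#'
#' One-time training on all non-holdout subjects and one-time evaluation on
#' the holdout, with no resampling or averaging.
#'
#' @param features_df trial feature table with a `label` column.
#' @param holdout_subject_ids subjects withheld for testing; default the
#'   first `floor(n/3)` subjects in table order.
#' @param seed integer seed (importance-ranking folds).
#' @inheritParams run_paradigm1
#' @return an [evaluation_report()] with the trained classifier attached as
#'   attribute `classifier`.
#' @export
run_paradigm2 <- function(features_df, holdout_subject_ids = NULL, seed = 1L,
                          mode = "pca", K = 20L, n_selected = NULL,
                          n_folds = 10L, n_resamples = 50L, cost = 1) {
  subjects <- unique(features_df$subject_id)
  if (is.null(holdout_subject_ids)) {
    holdout_subject_ids <- subjects[seq_len(floor(length(subjects) / 3))]
  }
  missing <- setdiff(holdout_subject_ids, subjects)
  if (length(missing) > 0L) {
    contract_error(sprintf("holdout subject(s) not in the data: %s",
                           paste(missing, collapse = ", ")))
  }
  train_subj <- setdiff(subjects, holdout_subject_ids)
  if (length(train_subj) == 0L) {
    contract_error("holdout covers all subjects; training set is empty")
  }
  train_df <- features_df[features_df$subject_id %in% train_subj, , drop = FALSE]
  test_df <- features_df[features_df$subject_id %in% holdout_subject_ids, , drop = FALSE]
  clf <- build_classifier(train_df, mode = mode, K = K, n_selected = n_selected,
                          n_folds = n_folds, n_resamples = n_resamples,
                          cost = cost, seed = seed)
  pc_tests <- if (mode == "pca") {
    pc_group_tests(clf$train_scores, clf$train_labels)
  } else {
    NULL
  }
  report <- evaluation_report(predict_trials(clf, test_df), pc_tests = pc_tests)
  attr(report, "classifier") <- clf
  report
}
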