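# Standardization + PCA, importance ranking, SVM training, prediction, and
# the two validation paradigms.

test_that("PCA on standardized features behaves as linear algebra dictates", {
  set.seed(1)
  iso <- matrix(rnorm(4000 * 25), ncol = 25)
  pc <- fit_standardizer_pca(iso, K = 25)
  expect_equal(pc$explained_variance_fractions,
               rep(1 / 25, 25), tolerance = 0.15)
  expect_equal(crossprod(pc$loadings), diag(25), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$explained_variance_fractions) <= 1e-12))
  expect_lte(sum(pc$explained_variance_fractions), 1 + 1e-9)

  # rank-2 data: two components carry everything
  set.seed(2)
  basis <- matrix(rnorm(2 * 25), 2, 25)
  rank2 <- matrix(rnorm(100 * 2), ncol = 2) %*% basis
  rank2 <- rank2 + matrix(rnorm(2500, sd = 1e-8), ncol = 25)
  pc2 <- fit_standardizer_pca(rank2, K = 5)
  expect_gt(sum(pc2$explained_variance_fractions[1:2]), 0.999)

  # K = 25 projection reconstructs the standardized data exactly
  set.seed(3)
  x <- matrix(rnorm(60 * 25), ncol = 25)
  pcf <- fit_standardizer_pca(x, K = 25)
  xs <- sweep(sweep(x, 2, pcf$feature_means), 2, pcf$feature_sds, `/`)
  expect_equal(project_features(pcf, x) %*% t(pcf$loadings), xs,
               tolerance = 1e-8, ignore_attr = TRUE)

  xconst <- x
  xconst[, 3] <- 2
  colnames(xconst) <- paste0("f", 1:25)
  err <- tryCatch(fit_standardizer_pca(xconst), error = identity)
  expect_s3_class(err, "eegdloc_standardization_error")
  expect_match(conditionMessage(err), "f3")
})

test_that("training-set PC scores are mutually uncorrelated", {
  set.seed(4)
  x <- matrix(rnorm(200 * 10), ncol = 10) %*% matrix(rnorm(100), 10)
  pc <- fit_standardizer_pca(x, K = 5)
  s <- project_features(pc, x)
  cc <- cor(s)
  expect_true(all(abs(cc[upper.tri(cc)]) < 1e-6))
})

test_that("importance ranking rewards separability and is seed-deterministic", {
  set.seed(5)
  n_subj <- 20
  labels_s <- rep(c("focal", "diffuse"), each = n_subj / 2)
  subject <- rep(sprintf("S%02d", 1:n_subj), each = 4)
  labels <- rep(labels_s, each = 4)
  perfect <- ifelse(labels == "focal", 1, 0) # separates exactly
  noise <- rnorm(length(labels))
  scores <- cbind(perfect = perfect, noise = noise)
  rk <- rank_importance(scores, labels, subject, seed = 7)
  expect_equal(unname(rk$scores["perfect"]), 1.0)
  # null AUCs on small subject folds are noisy but stay clearly below 1
  expect_lt(unname(rk$scores["noise"]), 0.85)
  expect_equal(rk$order[1], 1)
  rk2 <- rank_importance(scores, labels, subject, seed = 7)
  expect_identical(rk, rk2)
  rk3 <- rank_importance(scores, labels, subject, seed = 8)
  expect_false(identical(rk$scores, rk3$scores))
  expect_error(rank_importance(scores, rep("focal", length(labels)), subject),
               class = "eegdloc_ranking_error")
})

test_that("a label-independent component stays near the chance floor", {
  set.seed(6)
  n_subj <- 60
  subject <- rep(sprintf("S%02d", 1:n_subj), each = 2)
  labels <- rep(rep(c("focal", "diffuse"), each = n_subj / 2), each = 2)
  rk <- rank_importance(matrix(rnorm(length(labels)), ncol = 1),
                        labels, subject, n_resamples = 20, seed = 1)
  expect_lt(rk$scores[1], 0.35) # null |AUC-0.5|*2 on ~12-trial folds
})

test_that("the linear SVM separates separable clouds and matches e1071 decisions", {
  set.seed(7)
  x <- rbind(matrix(rnorm(60, mean = 2), ncol = 2),
             matrix(rnorm(60, mean = -2), ncol = 2))
  labels <- rep(c("focal", "diffuse"), each = 30)
  clf <- train_svm(x, labels)
  dv <- eegdloc:::svm_decision_values(clf, x)
  expect_equal(ifelse(dv >= 0, "focal", "diffuse"), labels)
  expect_gt(mean(dv[labels == "focal"]), 0)
  # affine reduction reproduces libsvm decision values
  fit <- e1071::svm(x, factor(labels, levels = c("diffuse", "focal")),
                    kernel = "linear", cost = 1, scale = FALSE)
  raw <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  expect_equal(abs(dv), abs(raw), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(train_svm(x, rep("focal", 60)), class = "eegdloc_training_error")
})

test_that("shuffled labels yield chance-level held-out accuracy", {
  feats <- make_feature_table(n_per_class = 12, trials = 2, sep = 3, seed = 8)
  set.seed(9)
  subj <- unique(feats$subject_id)
  shuffled <- setNames(sample(rep(c("focal", "diffuse"), length.out = length(subj))),
                       subj)
  feats$label <- unname(shuffled[feats$subject_id])
  res <- suppressMessages(
    run_paradigm1(feats, n_repetitions = 40, seed = 10, n_resamples = 10)
  )
  expect_gt(res$hard_accuracy, 0.25)
  expect_lt(res$hard_accuracy, 0.75)
})

test_that("prediction uses training-set parameters only", {
  feats <- make_feature_table(n_per_class = 10, trials = 3, sep = 4, seed = 11)
  subj <- unique(feats$subject_id)
  train <- feats[feats$subject_id %in% subj[1:14], ]
  test <- feats[!(feats$subject_id %in% subj[1:14]), ]
  clf <- suppressMessages(build_classifier(train, seed = 1, n_resamples = 5))
  # leakage detector: projecting shifted test data with training loadings must
  # differ from refitting PCA on the test data itself
  test_x <- eegdloc:::feature_matrix(test)
  shifted <- test_x + 5
  k <- min(clf$pc_model$K, nrow(shifted) - 1)
  proj_train <- project_features(clf$pc_model, shifted)[, 1:k]
  pc_refit <- fit_standardizer_pca(shifted, K = k)
  proj_refit <- project_features(pc_refit, shifted)[, 1:k]
  expect_gt(max(abs(proj_train - proj_refit)), 1)

  preds <- predict_trials(clf, test)
  expect_setequal(names(preds),
                  c("subject_id", "trial_index", "label", "predicted", "decision_value"))
  expect_true(all(preds$predicted[preds$decision_value >= 0] == "focal"))
  expect_true(all(preds$predicted[preds$decision_value < 0] == "diffuse"))
})

test_that("the leakage guard rejects any train/test subject overlap", {
  feats <- make_feature_table(n_per_class = 6, trials = 2, seed = 12)
  clf <- suppressMessages(build_classifier(feats, seed = 1, n_resamples = 5))
  expect_error(predict_trials(clf, feats[1:3, ]), class = "eegdloc_leakage_error")
})

test_that("paradigm 1 is reproducible and recovers strong separation", {
  feats <- make_feature_table(n_per_class = 9, trials = 2, sep = 4, seed = 13)
  r1 <- suppressMessages(run_paradigm1(feats, n_repetitions = 20, seed = 5,
                                       n_folds = 5, n_resamples = 10))
  r2 <- suppressMessages(run_paradigm1(feats, n_repetitions = 20, seed = 5,
                                       n_folds = 5, n_resamples = 10))
  expect_identical(r1$per_repetition, r2$per_repetition)
  expect_gte(r1$hard_accuracy, 0.9)
  expect_error(run_paradigm1(feats[feats$subject_id %in% c("S01", "S02", "S10"), ]),
               class = "eegdloc_contract_error")
})

test_that("paradigm 2 trains once on non-holdout subjects", {
  feats <- make_feature_table(n_per_class = 9, trials = 2, sep = 4, seed = 14)
  subj <- unique(feats$subject_id)
  hold <- subj[c(1:3, 10:12)] # mixed-class holdout
  rep2 <- suppressMessages(run_paradigm2(feats, holdout_subject_ids = hold,
                                         seed = 2, n_folds = 5, n_resamples = 10))
  expect_s3_class(rep2, "evaluation_report")
  expect_gte(rep2$hard_accuracy, 0.85)
  expect_setequal(rep2$per_subject$subject_id, hold)
  expect_true(all(rep2$per_subject$n_trials == 2))
  expect_error(run_paradigm2(feats, holdout_subject_ids = subj),
               class = "eegdloc_contract_error")
  expect_error(run_paradigm2(feats, holdout_subject_ids = "NOPE"),
               class = "eegdloc_contract_error")
})

test_that("raw-feature and PCA modes share the evaluation schema", {
  feats <- make_feature_table(n_per_class = 8, trials = 2, sep = 3, seed = 15)
  subj <- unique(feats$subject_id)
  hold <- subj[seq(1, 16, by = 3)]
  for (mode in c("pca", "raw_features")) {
    rep_ <- suppressMessages(run_paradigm2(feats, holdout_subject_ids = hold,
                                           seed = 3, mode = mode, n_resamples = 5))
    expect_s3_class(rep_, "evaluation_report")
    expect_true(is.numeric(rep_$hard_accuracy))
    clf <- attr(rep_, "classifier")
    expect_length(clf$selected_indices, if (mode == "pca") 6 else 10)
  }
})

test_that("classifiers serialize to JSON and predict identically after reload", {
  feats <- make_feature_table(n_per_class = 8, trials = 2, sep = 3, seed = 16)
  subj <- unique(feats$subject_id)
  train <- feats[feats$subject_id %in% subj[1:10], ]
  test <- feats[!(feats$subject_id %in% subj[1:10]), ]
  clf <- suppressMessages(build_classifier(train, seed = 4, n_resamples = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, path)
  back <- read_classifier(path)
  expect_equal(predict_trials(back, test)$decision_value,
               predict_trials(clf, test)$decision_value, tolerance = 1e-10)
})

test_that("the package AUC matches pROC on a fixture", {
  skip_if_not_installed("pROC")
  set.seed(17)
  score <- rnorm(50)
  pos <- runif(50) > 0.5
  ours <- eegdloc:::auc_score(score, pos)
  ref <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = score,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})
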