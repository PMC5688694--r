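# Classification: training-set standardization + PCA, cross-validated ROC
# importance ranking, and a linear SVM. All statistics (means, sds, loadings,
# importance, SVM weights) are estimated from training subjects only; a
# runtime leakage guard rejects any train/test subject overlap.

feature_matrix <- function(features_df) {
  cols <- grep("^f[0-9]+$", names(features_df), value = TRUE)
  as.matrix(features_df[, cols, drop = FALSE])
}

#' Fit a standardizer + PCA model on training trials
#'
#' Features are z-scored by training-set mean and standard deviation, then the
#' principal components of the standardized data are extracted; the top `K`
#' loadings are retained. Component signs are fixed (largest-magnitude loading
#' positive) so results are deterministic.
#'
#' @param train_features trials x features numeric matrix (or a feature
#'   data.frame from [cohort_features()]).
#' @param K number of components to retain (default 20; capped at the rank).
#' @return object of class `pc_model`: `feature_means`, `feature_sds`,
#'   `loadings` (features x K, orthonormal columns),
#'   `explained_variance_fractions` (all components), `K`.
#' @export
fit_standardizer_pca <- function(train_features, K = 20L) {
  x <- if (is.data.frame(train_features)) feature_matrix(train_features) else train_features
  if (nrow(x) < 2L) contract_error("PCA needs at least 2 training trials")
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  if (any(sdev < 1e-12)) {
    stop_eegdloc(
      sprintf("constant feature column(s): %s",
              paste(colnames(x)[sdev < 1e-12], collapse = ", ")),
      "eegdloc_standardization_error"
    )
  }
  xs <- sweep(sweep(x, 2, mu), 2, sdev, `/`)
  pr <- prcomp(xs, center = FALSE, scale. = FALSE)
  K <- min(as.integer(K), ncol(pr$rotation), nrow(x) - 1L)
  load <- pr$rotation[, seq_len(K), drop = FALSE]
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  evf <- pr$sdev^2 / sum(pr$sdev^2)
  structure(
    list(feature_means = mu, feature_sds = sdev, loadings = load,
         explained_variance_fractions = evf, K = K),
    class = "pc_model"
  )
}

#' Project trials onto a fitted PC model
#'
#' Standardizes with the training means/sds and projects onto the training
#' loadings — never refits on the data being projected.
#'
#' @param pc_model a [fit_standardizer_pca()] model.
#' @param features trials x features matrix or feature data.frame.
#' @return trials x K score matrix.
#' @export
project_features <- function(pc_model, features) {
  x <- if (is.data.frame(features)) feature_matrix(features) else features
  if (ncol(x) != length(pc_model$feature_means)) {
    contract_error("feature dimension mismatch between model and data")
  }
  xs <- sweep(sweep(x, 2, pc_model$feature_means), 2, pc_model$feature_sds, `/`)
  xs %*% pc_model$loadings
}

# Mann-Whitney AUC of a single score column for a binary label vector
# (focal = positive). Returns NA when either class is absent.
auc_score <- function(score, is_pos) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated univariate ROC importance of components
#'
#' For each component the importance is the scaled separability
#' `2 * |AUC - 0.5|` of that component alone as a predictor of the class
#' label, measured on held-out folds of a subject-level k-fold
#' cross-validation and averaged over folds and resamples. Scores lie in
#' `[0, 1]` (1 = the component alone separates the classes perfectly on every
#' held-out fold) and are deterministic given `seed`. If no fold ever
#' contains both classes (only possible for degenerately small cohorts) the
#' whole-sample AUC is used instead, with a message.
#'
#' @param component_scores trials x K numeric matrix.
#' @param labels per-trial class labels (`"focal"`/`"diffuse"`).
#' @param subject_ids per-trial subject identifiers; folds are formed at
#'   subject level.
#' @param n_folds folds per resample (default 10).
#' @param n_resamples number of fold resamplings (default 50).
#' @param seed integer seed.
#' @return object of class `importance_ranking`: `scores` (per component),
#'   `order` (component indices by descending score).
#' @export
rank_importance <- function(component_scores, labels, subject_ids,
                            n_folds = 10L, n_resamples = 50L, seed = 1L) {
  component_scores <- as.matrix(component_scores)
  if (length(unique(labels)) < 2L) {
    stop_eegdloc("importance ranking needs both classes", "eegdloc_ranking_error")
  }
  subjects <- unique(subject_ids)
  n_folds <- min(as.integer(n_folds), length(subjects))
  is_pos <- labels == "focal"
  k <- ncol(component_scores)
  acc <- matrix(0, nrow = n_resamples * n_folds, ncol = k)
  used <- logical(nrow(acc))
  fold_seeds <- derive_seeds(seed, n_resamples)
  row <- 0L
  for (r in seq_len(n_resamples)) {
    fold_of <- withr::with_seed(
      fold_seeds[r],
      sample(rep_len(seq_len(n_folds), length(subjects)))
    )
    for (f in seq_len(n_folds)) {
      row <- row + 1L
      test <- subject_ids %in% subjects[fold_of == f]
      if (!any(test)) next
      pos <- is_pos[test]
      if (all(pos) || !any(pos)) next
      aucs <- vapply(seq_len(k), function(j) {
        auc_score(component_scores[test, j], pos)
      }, numeric(1))
      acc[row, ] <- 2 * abs(aucs - 0.5)
      used[row] <- TRUE
    }
  }
  if (!any(used)) {
    # Degenerately small cohorts: every held-out fold was single-class, so no
    # cross-validated AUC exists. Fall back to the whole-training-set AUC.
    message("importance ranking: no fold contained both classes; using full-sample AUC")
    aucs <- vapply(seq_len(k), function(j) {
      auc_score(component_scores[, j], is_pos)
    }, numeric(1))
    acc <- matrix(2 * abs(aucs - 0.5), nrow = 1)
    used <- TRUE
  }
  scores <- colMeans(acc[used, , drop = FALSE])
  names(scores) <- colnames(component_scores) %||% paste0("PC", seq_len(k))
  structure(list(scores = scores, order = order(scores, decreasing = TRUE)),
            class = "importance_ranking")
}

#' Train a linear SVM on selected component scores
#'
#' Fits a linear-kernel support vector machine (cost parameter `cost`) and
#' reduces it to its explicit affine decision function `d(x) = x w + b`,
#' oriented so that positive decision values mean focal. A decision value of
#' exactly 0 is classified focal.
#'
#' @param selected_scores trials x n_selected numeric matrix.
#' @param labels per-trial labels (`"focal"`/`"diffuse"`), both present.
#' @param cost SVM cost parameter (default 1).
#' @return object of class `svm_decision`: `w`, `b`, `cost`.
#' @export
train_svm <- function(selected_scores, labels, cost = 1) {
  selected_scores <- as.matrix(selected_scores)
  y <- factor(labels, levels = c("diffuse", "focal"))
  if (any(is.na(y)) || length(unique(y)) < 2L) {
    stop_eegdloc("SVM training needs both classes", "eegdloc_training_error")
  }
  fit <- e1071::svm(selected_scores, y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients decision values so positive means the first class seen in
  # the data; flip if that class is diffuse so positive always means focal.
  pred <- predict(fit, selected_scores, decision.values = TRUE)
  dvname <- colnames(attr(pred, "decision.values"))[1]
  if (!startsWith(dvname, "focal")) {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, cost = cost), class = "svm_decision")
}

svm_decision_values <- function(clf, scores) {
  drop(as.matrix(scores) %*% clf$w + clf$b)
}

#' Train the full classification pipeline on training trials
#'
#' In `"pca"` mode: standardize, project onto the top-`K` principal
#' components, rank components by cross-validated ROC importance, keep the
#' `n_selected` most important, and train the linear SVM on those. In
#' `"raw_features"` mode the PCA rotation is skipped: standardized features
#' are ranked and selected directly.
#'
#' @param train_df training feature data.frame (subject_id, trial_index,
#'   label, f1..f25).
#' @param mode `"pca"` (default) or `"raw_features"`.
#' @param K principal components retained before selection (default 20).
#' @param n_selected components/features passed to the SVM (default 6 in PCA
#'   mode, 10 in raw-feature mode).
#' @param n_folds,n_resamples importance-ranking cross-validation settings.
#' @param cost SVM cost.
#' @param seed integer seed for the importance ranking.
#' @return object of class `trained_classifier`.
#' @export
build_classifier <- function(train_df, mode = c("pca", "raw_features"),
                             K = 20L, n_selected = NULL,
                             n_folds = 10L, n_resamples = 50L,
                             cost = 1, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(n_selected)) n_selected <- if (mode == "pca") 6L else 10L
  x <- feature_matrix(train_df)
  # a feature that is constant on the training trials (e.g. the slow-mode
  # count when no eigenvalue ever crosses the threshold) carries no
  # information and cannot be standardized; drop it from the model
  keep <- which(apply(x, 2, sd) >= 1e-12)
  if (length(keep) < ncol(x)) {
    message(sprintf("dropping constant feature column(s): %s",
                    paste(colnames(x)[-keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
  }
  if (mode == "pca") {
    pc <- fit_standardizer_pca(x, K = K)
    scores <- project_features(pc, x)
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  } else {
    pc <- fit_standardizer_pca(x, K = ncol(x)) # reuse standardizer stats
    scores <- sweep(sweep(x, 2, pc$feature_means), 2, pc$feature_sds, `/`)
  }
  ranking <- rank_importance(scores, train_df$label, train_df$subject_id,
                             n_folds = n_folds, n_resamples = n_resamples,
                             seed = seed)
  sel <- ranking$order[seq_len(min(n_selected, ncol(scores)))]
  svm <- train_svm(scores[, sel, drop = FALSE], train_df$label, cost = cost)
  structure(
    list(mode = mode, pc_model = if (mode == "pca") pc else NULL,
         feature_means = pc$feature_means, feature_sds = pc$feature_sds,
         feature_names = colnames(x),
         ranking = ranking, selected_indices = sel, svm = svm,
         train_subjects = unique(train_df$subject_id),
         train_scores = scores, train_labels = train_df$label),
    class = "trained_classifier"
  )
}

classifier_scores <- function(clf, features_df) {
  x <- feature_matrix(features_df)
  if (!is.null(clf$feature_names)) {
    missing <- setdiff(clf$feature_names, colnames(x))
    if (length(missing) > 0L) {
      contract_error(sprintf("test features lack column(s): %s",
                             paste(missing, collapse = ", ")))
    }
    x <- x[, clf$feature_names, drop = FALSE]
  }
  if (clf$mode == "pca") {
    project_features(clf$pc_model, x)
  } else {
    sweep(sweep(x, 2, clf$feature_means), 2, clf$feature_sds, `/`)
  }
}

#' Predict trial labels with a trained classifier
#'
#' Test trials are standardized and projected with training-set parameters
#' only. A runtime leakage guard aborts if any test subject was part of the
#' training set.
#'
#' @param clf a [build_classifier()] result.
#' @param test_df test feature data.frame.
#' @return data.frame: subject_id, trial_index, true label, predicted label,
#'   decision_value (positive = focal; ties at 0 go to focal).
#' @export
predict_trials <- function(clf, test_df) {
  overlap <- intersect(unique(test_df$subject_id), clf$train_subjects)
  if (length(overlap) > 0L) {
    stop_eegdloc(
      sprintf("leakage guard: subject(s) %s appear in both training and testing sets",
              paste(overlap, collapse = ", ")),
      "eegdloc_leakage_error"
    )
  }
  scores <- classifier_scores(clf, test_df)
  dv <- svm_decision_values(clf$svm, scores[, clf$selected_indices, drop = FALSE])
  data.frame(
    subject_id = test_df$subject_id,
    trial_index = test_df$trial_index,
    label = test_df$label,
    predicted = ifelse(dv >= 0, "focal", "diffuse"),
    decision_value = dv,
    stringsAsFactors = FALSE
  )
}

#' Serialize a trained classifier to JSON
#'
#' Writes the standardizer statistics, PCA loadings, selected indices and SVM
#' weights as a structured text container that [read_classifier()] restores.
#'
#' @param clf a `trained_classifier`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(clf, path) {
  obj <- list(
    package_version = as.character(packageVersion("eegdloc")),
    mode = clf$mode,
    feature_means = clf$feature_means,
    feature_sds = clf$feature_sds,
    feature_names = clf$feature_names,
    loadings = if (!is.null(clf$pc_model)) clf$pc_model$loadings else NULL,
    explained_variance_fractions =
      if (!is.null(clf$pc_model)) clf$pc_model$explained_variance_fractions else NULL,
    importance_scores = clf$ranking$scores,
    selected_indices = clf$selected_indices,
    svm_w = clf$svm$w, svm_b = clf$svm$b, svm_cost = clf$svm$cost,
    train_subjects = clf$train_subjects
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Restore a serialized classifier
#'
#' @param path JSON file written by [write_classifier()].
#' @return a `trained_classifier` usable with [predict_trials()].
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pc <- NULL
  if (!is.null(obj$loadings)) {
    pc <- structure(
      list(feature_means = obj$feature_means, feature_sds = obj$feature_sds,
           loadings = as.matrix(obj$loadings),
           explained_variance_fractions = obj$explained_variance_fractions,
           K = ncol(as.matrix(obj$loadings))),
      class = "pc_model"
    )
  }
  structure(
    list(mode = obj$mode, pc_model = pc,
         feature_means = obj$feature_means, feature_sds = obj$feature_sds,
         feature_names = obj$feature_names,
         ranking = structure(list(scores = obj$importance_scores,
                                  order = order(obj$importance_scores, decreasing = TRUE)),
                             class = "importance_ranking"),
         selected_indices = obj$selected_indices,
         svm = structure(list(w = obj$svm_w, b = obj$svm_b, cost = obj$svm_cost),
                         class = "svm_decision"),
         train_subjects = obj$train_subjects),
    class = "trained_classifier"
  )
}
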