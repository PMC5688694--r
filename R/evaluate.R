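# Classifier evaluation: trial-level (soft) and subject-level majority-vote
# (hard) accuracy, sensitivity/specificity with focal as the positive class,
# and per-component Welch t-tests.

#' Soft (trial-level) accuracy
#'
#' Fraction of trials whose predicted label matches the subject's true label;
#' no per-subject aggregation.
#'
#' @param predicted,truth aligned character vectors of trial labels.
#' @return fraction in `[0, 1]`.
#' @export
soft_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0L) {
    contract_error("predicted and true labels must be nonempty and aligned")
  }
  mean(predicted == truth)
}

#' Per-subject majority votes
#'
#' Aggregates per-trial predictions to one label per subject by majority
#' vote. An exact tie is resolved by the sign of the subject's mean SVM
#' decision value (non-negative mean goes to focal).
#'
#' @param predictions data.frame from [predict_trials()] (columns subject_id,
#'   label, predicted, decision_value).
#' @return data.frame: subject_id, true label, n_trials, focal_fraction,
#'   mean_decision_value, majority.
#' @export
subject_votes <- function(predictions) {
  sp <- split(predictions, predictions$subject_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    ff <- mean(d$predicted == "focal")
    mdv <- mean(d$decision_value)
    maj <- if (ff > 0.5) "focal" else if (ff < 0.5) "diffuse" else {
      if (mdv >= 0) "focal" else "diffuse"
    }
    data.frame(subject_id = d$subject_id[1], label = d$label[1],
               n_trials = nrow(d), focal_fraction = ff,
               mean_decision_value = mdv, majority = maj,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Hard (subject-level majority-vote) accuracy
#'
#' @param votes data.frame from [subject_votes()].
#' @return fraction of subjects whose majority label matches their true label.
#' @export
hard_accuracy <- function(votes) {
  if (nrow(votes) == 0L) contract_error("no subjects to evaluate")
  if (any(votes$n_trials < 1L)) contract_error("every subject needs >= 1 trial vote")
  mean(votes$majority == votes$label)
}

#' Sensitivity and specificity (focal = positive)
#'
#' Sensitivity = TP / (TP + FN) over truly focal subjects; specificity =
#' TN / (TN + FP) over truly diffuse subjects. A metric whose class is absent
#' from the true labels is returned as `NA` with a warning, never as a silent
#' zero.
#'
#' @param predicted,truth aligned label vectors (typically per-subject
#'   majorities).
#' @return named vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(predicted, truth) {
  if (length(predicted) != length(truth)) contract_error("label vectors must align")
  n_focal <- sum(truth == "focal")
  n_diffuse <- sum(truth == "diffuse")
  sens <- if (n_focal == 0L) {
    warning("no focal subjects among true labels; sensitivity undefined")
    NA_real_
  } else {
    sum(predicted == "focal" & truth == "focal") / n_focal
  }
  spec <- if (n_diffuse == 0L) {
    warning("no diffuse subjects among true labels; specificity undefined")
    NA_real_
  } else {
    sum(predicted == "diffuse" & truth == "diffuse") / n_diffuse
  }
  c(sensitivity = sens, specificity = spec)
}

#' Per-component two-sample Welch t-tests
#'
#' Compares the focal and diffuse distributions of each component score with
#' an unequal-variance (Welch) two-sample t-test at nominal level `alpha`,
#' without multiplicity correction (principal components are mutually
#' uncorrelated, so each test is read independently). A component with zero
#' variance in both groups is flagged and skipped.
#'
#' @param component_scores trials (or subjects) x K numeric matrix.
#' @param labels aligned class labels.
#' @param alpha nominal significance level (default 0.05).
#' @return data.frame: component, t, p, significant, skipped.
#' @export
pc_group_tests <- function(component_scores, labels, alpha = 0.05) {
  component_scores <- as.matrix(component_scores)
  g1 <- labels == "focal"
  g2 <- labels == "diffuse"
  if (sum(g1) < 2L || sum(g2) < 2L) {
    contract_error("each class needs >= 2 observations for the t-tests")
  }
  res <- lapply(seq_len(ncol(component_scores)), function(j) {
    a <- component_scores[g1, j]
    b <- component_scores[g2, j]
    if (sd(a) < 1e-12 && sd(b) < 1e-12) {
      return(data.frame(component = j, t = NA_real_, p = NA_real_,
                        significant = NA, skipped = TRUE))
    }
    tt <- t.test(a, b, var.equal = FALSE)
    data.frame(component = j, t = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < alpha, skipped = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assemble an evaluation report
#'
#' Bundles soft/hard accuracy, sensitivity, specificity and the per-subject
#' vote table for one train/test evaluation. The algebraic identity
#' `hard = (sensitivity * n_focal + specificity * n_diffuse) / n` is asserted
#' on construction whenever both classes are present.
#'
#' @param predictions per-trial predictions from [predict_trials()].
#' @param pc_tests optional [pc_group_tests()] table to attach.
#' @return object of class `evaluation_report`.
#' @export
evaluation_report <- function(predictions, pc_tests = NULL) {
  votes <- subject_votes(predictions)
  soft <- soft_accuracy(predictions$predicted, predictions$label)
  hard <- hard_accuracy(votes)
  ss <- suppressWarnings(sensitivity_specificity(votes$majority, votes$label))
  n_focal <- sum(votes$label == "focal")
  n_diffuse <- sum(votes$label == "diffuse")
  if (n_focal > 0L && n_diffuse > 0L) {
    identity_val <- (ss["sensitivity"] * n_focal + ss["specificity"] * n_diffuse) /
      (n_focal + n_diffuse)
    stopifnot(abs(hard - identity_val) < 1e-12)
  }
  structure(
    list(soft_accuracy = soft, hard_accuracy = hard,
         sensitivity = unname(ss["sensitivity"]),
         specificity = unname(ss["specificity"]),
         n_focal_subjects = n_focal, n_diffuse_subjects = n_diffuse,
         per_subject = votes, per_trial = predictions,
         per_pc_tests = pc_tests),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %d subjects (%d focal / %d diffuse), %d trials\n  hard accuracy %.3f | soft accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
    nrow(x$per_subject), x$n_focal_subjects, x$n_diffuse_subjects,
    nrow(x$per_trial), x$hard_accuracy, x$soft_accuracy,
    x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' Serialize / restore an evaluation report
#'
#' Reports round-trip losslessly through JSON.
#'
#' @param report an `evaluation_report`.
#' @param path file path.
#' @return `path` (write) or the restored report (read).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_subject <- as.data.frame(obj$per_subject)
  obj$per_trial <- as.data.frame(obj$per_trial)
  if (!is.null(obj$per_pc_tests)) obj$per_pc_tests <- as.data.frame(obj$per_pc_tests)
  structure(obj, class = "evaluation_report")
}
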