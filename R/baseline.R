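#' Train the conventional machine-learning baseline classifier
#'
#' The comparison baseline: a support vector machine (RBF kernel by
#' default) fitted on the full per-window feature table with a seeded,
#' stratified 70/30 train/validation split. Missing feature values are
#' imputed by training-set column means; constant columns are dropped.
#'
#' @param features Feature table from [extract_features()].
#' @param labels Per-window ground-truth quadrant labels.
#' @param split Training fraction in (0, 1) (default 0.7).
#' @param seed Seed for the stratified split (and any kernel randomness).
#' @param kernel,cost,gamma Passed to [e1071::svm()]; `gamma = NULL` uses
#'   that function's 1/ncol default.
#' @return A `baseline_model`: list with the fitted `model`, feature
#'   names, imputation means, split indices, and validation accuracy.
#' @export
train_baseline <- function(features, labels, split = 0.7, seed = 1L,
                           kernel = "radial", cost = 1, gamma = NULL) {
  if (split <= 0 || split >= 1) invalid_argument("`split` must be in (0, 1)")
  labels <- factor(as.character(labels))
  X <- as.data.frame(features)
  X <- X[, setdiff(names(X), c("window", "eda_n_min", "eda_n_max")), drop = FALSE]
  if (nrow(X) != length(labels)) {
    invalid_argument("`labels` must have one entry per feature-table row")
  }
  counts <- table(labels)
  if (any(counts < 10L)) {
    invalid_argument(sprintf(
      "need >= 10 windows per class; too few: %s",
      paste(names(counts)[counts < 10L], collapse = ", ")
    ))
  }
  train_idx <- with_seed(sub_seed(seed, 301L), {
    sort(unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, round(split * length(idx)))
    })))
  })
  if (length(unique(labels[train_idx])) < nlevels(labels)) {
    stop_affect("a class is absent from the training split",
                "affectstream_stratification_error")
  }
  mu <- vapply(X[train_idx, , drop = FALSE], function(col) mean(col, na.rm = TRUE), numeric(1))
  impute <- function(df) {
    for (j in names(df)) {
      nas <- !is.finite(df[[j]])
      if (any(nas)) df[[j]][nas] <- mu[[j]]
    }
    df
  }
  Xtr <- impute(X[train_idx, , drop = FALSE])
  keep <- names(Xtr)[vapply(Xtr, function(col) stats::sd(col) > 0, logical(1))]
  Xtr <- Xtr[, keep, drop = FALSE]
  model <- with_seed(sub_seed(seed, 302L), {
    if (is.null(gamma)) {
      e1071::svm(x = Xtr, y = labels[train_idx], kernel = kernel, cost = cost, scale = TRUE)
    } else {
      e1071::svm(x = Xtr, y = labels[train_idx], kernel = kernel, cost = cost,
                 gamma = gamma, scale = TRUE)
    }
  })
  val_idx <- setdiff(seq_len(nrow(X)), train_idx)
  Xval <- impute(X[val_idx, , drop = FALSE])[, keep, drop = FALSE]
  val_pred <- as.character(predict(model, Xval))
  structure(
    list(
      model = model, feature_names = keep, impute_means = mu,
      train_idx = train_idx, val_idx = val_idx,
      levels = levels(labels), split = split, seed = seed,
      validation_accuracy = mean(val_pred == as.character(labels[val_idx]))
    ),
    class = "baseline_model"
  )
}

#' Predict quadrants with a trained baseline model
#'
#' @param object A `baseline_model` from [train_baseline()].
#' @param features Feature table for new windows.
#' @param ... Unused.
#' @return Character vector of predicted quadrant labels.
#' @export
predict.baseline_model <- function(object, features, ...) {
  X <- as.data.frame(features)
  missing_cols <- setdiff(object$feature_names, names(X))
  if (length(missing_cols) > 0L) {
    invalid_argument(sprintf("feature table lacks columns: %s",
                             paste(utils::head(missing_cols, 5), collapse = ", ")))
  }
  X <- X[, object$feature_names, drop = FALSE]
  for (j in names(X)) {
    nas <- !is.finite(X[[j]])
    if (any(nas)) X[[j]][nas] <- object$impute_means[[j]]
  }
  as.character(predict(object$model, X))
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf(
    "<baseline_model> SVM on %d features; %d train / %d validation windows; validation accuracy %.3f\n",
    length(x$feature_names), length(x$train_idx), length(x$val_idx), x$validation_accuracy
  ))
  invisible(x)
}

#' Head-to-head comparison of the two judgment approaches
#'
#' Runs the rule-based judge (optimal-feature approach) and a trained SVM
#' baseline on the same windows of a labelled session and tabulates, for
#' each approach, the per-quadrant adaptation-event activation counts
#' (total and matching the ground-truth label), the decision accuracy,
#' and the confusion matrix. The baseline is typically trained on a
#' different subject's session (cross-subject protocol) or on the same
#' session's 70% split (within-subject), whichever the caller supplies.
#'
#' @param session Labelled (synthetic) session to evaluate; preprocessed
#'   internally.
#' @param baseline A trained `baseline_model`.
#' @param calibration_windows Calibration prefix for the rule-based judge;
#'   the same windows are excluded from the baseline's scoring so both
#'   approaches are scored on identical windows.
#' @param persistence,refractory Passed to [policy_step()].
#' @return A `comparison_result` list with per-approach elements
#'   (`accuracy`, `activations`, `correct_activations`, `confusion`) and
#'   the evaluated window count.
#' @export
compare_approaches <- function(session, baseline, calibration_windows = 4,
                               persistence = 1, refractory = 1) {
  if (!inherits(baseline, "baseline_model")) {
    stop_affect("`baseline` must be a trained baseline_model", "affectstream_state_error")
  }
  prep <- preprocess_session(session)
  feats <- extract_features(prep)
  labels <- session$labels[feats$window + 1L]
  rules <- judge_session(prep, calibration_windows = calibration_windows, features = feats)
  keep <- !rules$calibration
  if (!any(keep)) invalid_argument("no post-calibration windows to compare")
  truth <- labels[keep]
  quads <- c("HAPV", "HANV", "LANV", "LAPV")

  score <- function(pred) {
    ev <- policy_step(pred, persistence = persistence, refractory = refractory)
    act <- table(factor(ev$events$quadrant, levels = quads))
    correct <- table(factor(
      ev$events$quadrant[ev$events$quadrant == truth[ev$events$step]],
      levels = quads
    ))
    list(
      accuracy = mean(pred == truth),
      confusion = table(truth = factor(truth, levels = quads),
                        predicted = factor(pred, levels = c(quads, "UNDECIDED"))),
      activations = as.integer(act),
      correct_activations = as.integer(correct)
    )
  }
  out <- list(
    quadrants = quads,
    n_windows = sum(keep),
    rule_based = score(rules$quadrant[keep]),
    baseline = score(predict(baseline, feats[keep, , drop = FALSE])),
    baseline_validation_accuracy = baseline$validation_accuracy
  )
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d judged windows\n", x$n_windows))
  cat(sprintf("  rule-based:  accuracy %.3f, activations (%s) = %s (correct %s)\n",
              x$rule_based$accuracy, paste(x$quadrants, collapse = "/"),
              paste(x$rule_based$activations, collapse = "/"),
              paste(x$rule_based$correct_activations, collapse = "/")))
  cat(sprintf("  SVM baseline: accuracy %.3f, activations = %s (correct %s)\n",
              x$baseline$accuracy,
              paste(x$baseline$activations, collapse = "/"),
              paste(x$baseline$correct_activations, collapse = "/")))
  invisible(x)
}
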