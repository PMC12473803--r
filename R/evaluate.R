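#' Classification metrics from a confusion matrix
#'
#' PD is the positive class. Precision = TP/(TP+FP), recall (= sensitivity)
#' = TP/(TP+FN), specificity = TN/(TN+FP), F1 the harmonic mean of
#' precision and recall. Undefined ratios (zero denominators) are reported
#' as `NA` except F1, which is 0 when there are neither predicted nor true
#' positives.
#'
#' @param tn,fp,fn,tp Confusion matrix counts (PD positive).
#' @return Named list: `accuracy`, `precision`, `recall`, `sensitivity`,
#'   `specificity`, `f1`.
#' @export
classification_metrics <- function(tn, fp, fn, tp) {
  tn <- unname(tn); fp <- unname(fp); fn <- unname(fn); tp <- unname(tp)
  n <- tn + fp + fn + tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  list(
    accuracy = (tp + tn) / n,
    precision = precision,
    recall = recall,
    sensitivity = recall,
    specificity = specificity,
    f1 = f1
  )
}

confusion_counts <- function(truth, pred) {
  c(
    tn = sum(pred == "Control" & truth == "Control"),
    fp = sum(pred == "PD" & truth == "Control"),
    fn = sum(pred == "Control" & truth == "PD"),
    tp = sum(pred == "PD" & truth == "PD")
  )
}

# precision-recall curve points over descending score thresholds
pr_curve <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord] == "PD"
  tp <- cumsum(truth)
  fp <- cumsum(!truth)
  npos <- sum(truth)
  keep <- c(diff(score[ord]) != 0, TRUE)  # one point per distinct threshold
  data.frame(
    recall = tp[keep] / npos,
    precision = tp[keep] / (tp[keep] + fp[keep])
  )
}

#' Refit a model on the full training set and evaluate once on the test set
#'
#' The pipeline (median imputation, z-scoring for scale-sensitive models,
#' the classifier restricted to the selected features) is refit on the
#' complete training set; the untouched test set is scored exactly once.
#' ROC-AUC uses continuous scores: class-PD probabilities for every family
#' (the SVM is probability-calibrated at this final refit).
#'
#' @param train,test Scenario feature tables from [make_split()].
#' @param model Model family string.
#' @param features Character vector of selected feature column names.
#' @param selection Optional result of [select_features()] whose `best_k`
#'   and per-k curve are carried into the report.
#' @return An `evaluation_report`: confusion counts, metrics, ROC-AUC, ROC
#'   and precision-recall curve points, the model specification and the
#'   selected features.
#' @export
evaluate_model <- function(train, test, model, features, selection = NULL) {
  spec <- model_spec(model)
  stopifnot(all(features %in% colnames(train)),
            all(features %in% colnames(test)))
  Xtr <- as.matrix(train[, features, drop = FALSE])
  Xte <- as.matrix(test[, features, drop = FALSE])
  ytr <- as_group_factor(train$group)
  yte <- as_group_factor(test$group)

  med <- col_medians(Xtr)
  Xtr <- impute_cols(Xtr, med)
  Xte <- impute_cols(Xte, med)
  if (spec$scaled) {
    zs <- zscore_fit(Xtr)
    Xtr <- zscore_apply(Xtr, zs)
    Xte <- zscore_apply(Xte, zs)
  }

  fit <- fit_final_model(model, Xtr, ytr)
  pred <- predict_final_model(fit, Xte)
  cm <- confusion_counts(yte, pred$labels)
  metrics <- classification_metrics(cm["tn"], cm["fp"], cm["fn"], cm["tp"])

  roc <- pROC::roc(
    response = yte, predictor = pred$score,
    levels = GROUP_LEVELS, direction = "<", quiet = TRUE
  )
  structure(
    list(
      model = model, label = spec$label, spec = spec,
      features = features,
      best_k = if (!is.null(selection)) selection$best_k else length(features),
      cv_path = if (!is.null(selection)) selection$path else NULL,
      confusion = cm,
      metrics = metrics,
      auc = as.numeric(pROC::auc(roc)),
      roc = data.frame(
        fpr = 1 - roc$specificities,
        tpr = roc$sensitivities
      ),
      pr = pr_curve(yte, pred$score),
      scores = pred$score,
      truth = yte,
      n_test = length(yte)
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    paste0(
      "<evaluation_report> %s (k = %d)\n",
      "  confusion: TN=%d FP=%d FN=%d TP=%d\n",
      "  accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | ",
      "specificity %.3f | ROC-AUC %.3f\n"
    ),
    x$label, x$best_k,
    x$confusion["tn"], x$confusion["fp"], x$confusion["fn"], x$confusion["tp"],
    m$accuracy, m$precision, m$recall, m$f1, m$specificity, x$auc
  ))
  invisible(x)
}

#' Cross-model consensus feature table
#'
#' Tallies, over a set of model evaluation reports, which features each
#' model's sequential forward selection retained, and reports the features
#' selected by at least `min_models` models, sorted by the number of
#' selecting models (descending) and annotated with the registry domain.
#'
#' @param reports List of `evaluation_report`s (>= 2).
#' @param min_models Minimum number of selecting models (default 3).
#' @return Data frame: `feature`, `models` (comma-separated labels),
#'   `n_models`, `domain`, `aggregation` (`Average`/`Asymmetry`).
#' @export
consensus_features <- function(reports, min_models = 3L) {
  stopifnot(length(reports) >= 2L)
  tally <- list()
  for (r in reports) {
    for (f in r$features) tally[[f]] <- c(tally[[f]], r$label)
  }
  if (!length(tally)) {
    return(data.frame(
      feature = character(), models = character(), n_models = integer(),
      domain = character(), aggregation = character()
    ))
  }
  base <- sub("\u2014(Average|Asymmetry)$", "", names(tally))
  agg <- sub("^.*\u2014", "", names(tally))
  domain <- registry_lookup(base)$domain
  out <- data.frame(
    feature = names(tally),
    models = vapply(tally, paste, "", collapse = ", "),
    n_models = lengths(tally),
    domain = domain,
    aggregation = agg,
    stringsAsFactors = FALSE
  )
  out <- out[out$n_models >= min_models, , drop = FALSE]
  out <- out[order(-out$n_models, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
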