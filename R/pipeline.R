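#' Run the full fixed-protocol classifier benchmark
#'
#' One participant-level stratified 80/20 split (reused across all models),
#' per-model sequential forward selection with 5-fold inner CV scored by
#' F1 and grid search over the subset size, final refit on the complete
#' training set and a single held-out evaluation per model, plus the
#' cross-model consensus-feature table.
#'
#' @param table Scenario feature table ([cohort_feature_table()] /
#'   [build_scenario_table()]).
#' @param models Model families to benchmark (default all five).
#' @param split_seed Seed of the participant-level split.
#' @param k_grid Grid of candidate feature counts (default `1:36`).
#' @param inner_folds Inner CV folds (default 5).
#' @param consensus_min Minimum number of selecting models for the
#'   consensus table (default 3).
#' @return An object of class `benchmark_result`: named list `reports` (one
#'   `evaluation_report` per model), `consensus`, `split`.
#' @export
run_benchmark <- function(table,
                          models = c("svm", "lr", "rf", "knn", "nb"),
                          split_seed = 42L, k_grid = 1:36,
                          inner_folds = 5L, consensus_min = 3L) {
  models <- match.arg(models, several.ok = TRUE)
  split <- make_split(table, 0.2, split_seed)
  reports <- list()
  for (m in models) {
    sel <- select_features(split$train, m, k_grid = k_grid,
                           inner_folds = inner_folds)
    reports[[m]] <- evaluate_model(split$train, split$test, m,
                                   sel$features, selection = sel)
  }
  structure(
    list(
      reports = reports,
      consensus = if (length(reports) >= 2L) {
        consensus_features(reports, consensus_min)
      } else {
        NULL
      },
      split = split
    ),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d model(s), %d train / %d test participants\n",
              length(x$reports), nrow(x$split$train), nrow(x$split$test)))
  for (r in x$reports) {
    m <- r$metrics
    cat(sprintf(
      "  %-11s k=%2d  acc %.3f  prec %.3f  rec %.3f  F1 %.3f  AUC %.3f\n",
      r$label, r$best_k, m$accuracy, m$precision, m$recall, m$f1, r$auc
    ))
  }
  invisible(x)
}
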