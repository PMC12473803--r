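# Sequential forward selection with 5-fold inner cross-validation scored by
# F1 (positive class PD). The greedy path is nested: the subset of size k
# extends the subset of size k-1 by the single feature with the largest mean
# inner-CV F1, so one pass to max(k_grid) yields the whole per-k curve.
# Preprocessing (median imputation; z-scoring for scale-sensitive models) is
# fit on each fold's training part only -- test rows never enter selection.

f1_score <- function(truth, pred) {
  tp <- sum(pred == "PD" & truth == "PD")
  fp <- sum(pred == "PD" & truth == "Control")
  fn <- sum(pred == "Control" & truth == "PD")
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

col_medians <- function(X) apply(X, 2, stats::median, na.rm = TRUE)

impute_cols <- function(X, med) {
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- med[nas[, 2]]
  X
}

zscore_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

zscore_apply <- function(X, zs) sweep(sweep(X, 2, zs$mu), 2, zs$sd, "/")

#' Sequential forward feature selection for one model
#'
#' Greedy forward selection embedded in stratified 5-fold inner
#' cross-validation scored by F1, with the number of features chosen by
#' grid search: `best_k` is the smallest `k` in `k_grid` attaining the
#' maximal mean inner-CV F1 (greedy-gain ties break toward the earlier
#' registry column). Fold preprocessing (column-median imputation; z-scoring
#' for SVM, LR and k-NN) is fit on fold-training data only.
#'
#' @param train Training scenario feature table (see [make_split()]).
#' @param model Model family: `"svm"`, `"lr"`, `"rf"`, `"knn"`, `"nb"`.
#' @param k_grid Integer grid of candidate subset sizes (default `1:36`,
#'   at most 25% of the 144 features).
#' @param inner_folds Number of inner CV folds (default 5).
#' @param fold_seed Seed for the stratified fold assignment (default 42).
#' @return List with `model`, `best_k`, `features` (the selected subset of
#'   size `best_k`, in selection order) and `path` (data frame: `k`,
#'   `feature`, `mean_f1`, `sd_f1` along the full greedy path).
#' @export
select_features <- function(train, model = c("svm", "lr", "rf", "knn", "nb"),
                            k_grid = 1:36, inner_folds = 5L,
                            fold_seed = 42L) {
  model <- match.arg(model)
  spec <- model_spec(model)
  feat_names <- intersect(scenario_feature_names(), colnames(train))
  if (!length(feat_names)) stop("no scenario feature columns in `train`")
  k_grid <- sort(unique(as.integer(k_grid)))
  if (!length(k_grid) || min(k_grid) < 1L) stop("`k_grid` must be non-empty positive")
  if (max(k_grid) > length(feat_names)) {
    stop("max(k_grid) exceeds the number of available features")
  }
  X <- as.matrix(train[, feat_names, drop = FALSE])
  y <- as_group_factor(train$group)
  if (any(table(y) < inner_folds)) {
    stop("each class needs at least `inner_folds` training participants")
  }
  fold_id <- stratified_folds(y, inner_folds, fold_seed)

  folds <- lapply(seq_len(inner_folds), function(f) {
    tr <- which(fold_id != f)
    val <- which(fold_id == f)
    if (length(unique(y[tr])) < 2L || length(unique(y[val])) < 2L) {
      stop(sprintf("inner fold %d is single-class", f))
    }
    med <- col_medians(X[tr, , drop = FALSE])
    Xtr <- impute_cols(X[tr, , drop = FALSE], med)
    Xval <- impute_cols(X[val, , drop = FALSE], med)
    if (spec$scaled) {
      zs <- zscore_fit(Xtr)
      Xtr <- zscore_apply(Xtr, zs)
      Xval <- zscore_apply(Xval, zs)
    }
    list(Xtr = Xtr, Xval = Xval, ytr = y[tr], yval = y[val])
  })

  p <- length(feat_names)
  k_max <- max(k_grid)
  sel <- integer(0)
  remaining <- seq_len(p)
  path <- data.frame(
    k = integer(k_max), feature = character(k_max),
    mean_f1 = numeric(k_max), sd_f1 = numeric(k_max),
    stringsAsFactors = FALSE
  )

  # incremental state for the decomposable families
  state <- init_sfs_state(model, folds)

  for (step in seq_len(k_max)) {
    f1s <- score_candidates(model, folds, sel, remaining, state)
    mean_f1 <- colMeans(f1s)
    best_j <- which.max(mean_f1)      # ties -> earliest registry column
    best <- remaining[best_j]
    path$k[step] <- step
    path$feature[step] <- feat_names[best]
    path$mean_f1[step] <- mean_f1[best_j]
    path$sd_f1[step] <- stats::sd(f1s[, best_j])
    state <- update_sfs_state(model, folds, state, best)
    sel <- c(sel, best)
    remaining <- remaining[-best_j]
  }

  in_grid <- path$mean_f1[k_grid]
  best_k <- k_grid[which.max(in_grid)]  # ties -> smallest k
  list(
    model = model, best_k = best_k,
    features = path$feature[seq_len(best_k)],
    path = path
  )
}

init_sfs_state <- function(model, folds) {
  if (model == "nb") {
    lapply(folds, function(fd) {
      p <- ncol(fd$Xtr)
      eps <- 1e-9 * max(apply(fd$Xtr, 2, function(c) mean((c - mean(c))^2)), 0)
      contrib <- array(0, dim = c(nrow(fd$Xval), p, 2L))
      base <- matrix(0, nrow(fd$Xval), 2L)
      for (gi in 1:2) {
        g <- GROUP_LEVELS[gi]
        Xi <- fd$Xtr[fd$ytr == g, , drop = FALSE]
        mu <- colMeans(Xi)
        v <- apply(Xi, 2, function(c) mean((c - mean(c))^2)) + eps + 1e-300
        centered <- sweep(fd$Xval, 2, mu)
        contrib[, , gi] <- -0.5 * (sweep(centered^2, 2, v, "/") +
          matrix(log(2 * pi * v), nrow(fd$Xval), p, byrow = TRUE))
        base[, gi] <- log(nrow(Xi) / nrow(fd$Xtr))
      }
      list(contrib = contrib, base = base)
    })
  } else if (model == "knn") {
    lapply(folds, function(fd) {
      list(D2 = matrix(0, nrow(fd$Xval), nrow(fd$Xtr)))
    })
  } else {
    NULL
  }
}

update_sfs_state <- function(model, folds, state, chosen) {
  if (model == "nb") {
    for (i in seq_along(folds)) {
      state[[i]]$base <- state[[i]]$base + state[[i]]$contrib[, chosen, ]
    }
  } else if (model == "knn") {
    for (i in seq_along(folds)) {
      fd <- folds[[i]]
      state[[i]]$D2 <- state[[i]]$D2 +
        outer(fd$Xval[, chosen], fd$Xtr[, chosen], "-")^2
    }
  }
  state
}

score_candidates <- function(model, folds, sel, remaining, state) {
  nf <- length(folds)
  f1s <- matrix(0, nf, length(remaining))
  for (i in seq_len(nf)) {
    fd <- folds[[i]]
    if (model == "nb") {
      st <- state[[i]]
      for (j in seq_along(remaining)) {
        lp <- st$base + st$contrib[, remaining[j], ]
        pred <- GROUP_LEVELS[max.col(lp, ties.method = "first")]
        f1s[i, j] <- f1_score(fd$yval, pred)
      }
    } else if (model == "knn") {
      st <- state[[i]]
      is_pd <- fd$ytr == "PD"
      nval <- nrow(fd$Xval)
      for (j in seq_along(remaining)) {
        cand <- remaining[j]
        D2 <- st$D2 + outer(fd$Xval[, cand], fd$Xtr[, cand], "-")^2
        pred <- character(nval)
        for (v in seq_len(nval)) {
          nn <- order(D2[v, ])[1:5]
          pred[v] <- if (sum(is_pd[nn]) > 2.5) "PD" else "Control"
        }
        f1s[i, j] <- f1_score(fd$yval, pred)
      }
    } else {
      for (j in seq_along(remaining)) {
        cols <- c(sel, remaining[j])
        pred <- fit_predict_labels(
          model,
          fd$Xtr[, cols, drop = FALSE], fd$ytr,
          fd$Xval[, cols, drop = FALSE]
        )
        f1s[i, j] <- f1_score(fd$yval, pred)
      }
    }
  }
  f1s
}
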