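# Model families of the fixed benchmarking protocol. Hyperparameters are
# frozen (the protocol does no tuning beyond the feature count):
#   SVM-RBF     cost = 1, gamma = "scale" (1 / (p * var(X))), balanced class
#               weights, probability outputs at final refit, seed 42
#   LR          L2-penalised logistic (C = 1), balanced weights, IRLS
#   RF          100 trees, balanced class weights, seed 42
#   k-NN        5 neighbours, uniform weights, Euclidean metric
#   Gaussian NB variance smoothing 1e-9 (times the largest feature variance)
# Scale-sensitive families (SVM, LR, k-NN) receive within-pipeline z-scoring
# fit on training data only; RF and NB run unscaled.

MODEL_FAMILIES <- c(svm = "SVM-RBF", lr = "LR", rf = "RF",
                    knn = "k-NN", nb = "Gaussian NB")

#' Model specification for the benchmark
#'
#' @param family One of `"svm"`, `"lr"`, `"rf"`, `"knn"`, `"nb"`.
#' @return List with `family`, display `label`, `scaled` (whether the model
#'   consumes z-scored features) and the frozen hyperparameters.
#' @export
model_spec <- function(family = c("svm", "lr", "rf", "knn", "nb")) {
  family <- match.arg(family)
  hyper <- switch(family,
    svm = list(cost = 1, gamma = "scale", class_weight = "balanced",
               probability = TRUE, seed = 42L),
    lr = list(C = 1, solver = "irls-ridge", max_iter = 100L,
              class_weight = "balanced", seed = 42L),
    rf = list(n_estimators = 100L, class_weight = "balanced", seed = 42L),
    knn = list(n_neighbors = 5L, weights = "uniform", metric = "euclidean"),
    nb = list(var_smoothing = 1e-9)
  )
  list(
    family = family, label = MODEL_FAMILIES[[family]],
    scaled = family %in% c("svm", "lr", "knn"),
    hyperparameters = hyper
  )
}

GROUP_LEVELS <- c("Control", "PD")

as_group_factor <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), GROUP_LEVELS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  factor(y, levels = GROUP_LEVELS)
}

balanced_obs_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  as.numeric(w[as.character(y)])
}

sk_scale_gamma <- function(X) {
  v <- mean((X - mean(X))^2)
  if (v <= 0) v <- 1
  1 / (ncol(X) * v)
}

# ---- L2-penalised logistic regression (IRLS) -------------------------------

fit_lr <- function(X, y, C = 1, maxit = 100L, tol = 1e-9) {
  y01 <- as.integer(y) - 1L
  w <- balanced_obs_weights(y)
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- diag(c(0, rep(1 / C, p - 1L)), p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    wt <- w * mu * (1 - mu)
    wt[wt < 1e-10] <- 1e-10
    z <- eta + (y01 - mu) / pmax(mu * (1 - mu), 1e-10)
    xtw <- t(Xd * wt)
    bnew <- tryCatch(
      drop(solve(xtw %*% Xd + pen, xtw %*% z)),
      error = function(e) beta
    )
    delta <- max(abs(bnew - beta))
    beta <- bnew
    if (delta < tol) break
  }
  structure(list(beta = beta), class = "tugcop_lr")
}

predict_lr <- function(fit, X) {
  stats::plogis(drop(cbind(1, X) %*% fit$beta))
}

# ---- Gaussian naive Bayes ---------------------------------------------------

fit_nb <- function(X, y, var_smoothing = 1e-9) {
  eps <- var_smoothing * max(apply(X, 2, function(c) mean((c - mean(c))^2)), 0)
  stats_by <- lapply(GROUP_LEVELS, function(g) {
    Xi <- X[y == g, , drop = FALSE]
    list(
      mu = colMeans(Xi),
      var = apply(Xi, 2, function(c) mean((c - mean(c))^2)) + eps + 1e-300,
      logprior = log(nrow(Xi) / nrow(X))
    )
  })
  names(stats_by) <- GROUP_LEVELS
  structure(list(classes = stats_by), class = "tugcop_nb")
}

nb_log_posterior <- function(fit, X) {
  sapply(GROUP_LEVELS, function(g) {
    s <- fit$classes[[g]]
    centered <- sweep(X, 2, s$mu)
    ll <- -0.5 * (sweep(centered^2, 2, s$var, "/") +
                    matrix(log(2 * pi * s$var), nrow(X), ncol(X), byrow = TRUE))
    rowSums(ll) + s$logprior
  })
}

predict_nb <- function(fit, X) {
  lp <- nb_log_posterior(fit, as.matrix(X))
  m <- apply(lp, 1, max)
  post <- exp(lp - m)
  post <- post / rowSums(post)
  list(
    labels = factor(GROUP_LEVELS[max.col(lp, ties.method = "first")],
                    levels = GROUP_LEVELS),
    score = post[, "PD"]
  )
}

# ---- k-NN from squared distances -------------------------------------------

# deterministic 5-NN vote (uniform weights, Euclidean); distance ties broken
# by training-row order so selection and evaluation are reproducible
knn_vote <- function(D2, ytr, k = 5L) {
  is_pd <- ytr == "PD"
  votes <- apply(D2, 1, function(r) {
    nn <- order(r)[seq_len(k)]
    sum(is_pd[nn])
  })
  list(
    labels = factor(ifelse(votes > k / 2, "PD", "Control"),
                    levels = GROUP_LEVELS),
    score = votes / k
  )
}

sq_dist <- function(A, B) {
  # rows of A vs rows of B
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
}

# ---- unified label-only fit/predict used inside SFS scoring ----------------

all_constant <- function(X) {
  all(X == rep(X[1, ], each = nrow(X)))
}

# an all-constant design carries no information; predict the (first-level on
# ties) training majority rather than handing degenerate input to a fitter
# (randomForest in particular does not terminate on constant-only matrices)
majority_labels <- function(ytr, n) {
  tab <- table(ytr)
  factor(rep(names(tab)[which.max(tab)], n), levels = GROUP_LEVELS)
}

fit_predict_labels <- function(family, Xtr, ytr, Xval) {
  if (all_constant(Xtr)) return(majority_labels(ytr, nrow(Xval)))
  switch(family,
    svm = {
      cw <- table(ytr)
      cw <- length(ytr) / (length(cw) * cw)
      fit <- e1071::svm(
        Xtr, ytr, kernel = "radial", cost = 1,
        gamma = sk_scale_gamma(Xtr),
        class.weights = cw, scale = FALSE, probability = FALSE
      )
      stats::predict(fit, Xval)
    },
    lr = {
      pr <- predict_lr(fit_lr(Xtr, ytr), Xval)
      factor(ifelse(pr >= 0.5, "PD", "Control"), levels = GROUP_LEVELS)
    },
    rf = {
      set.seed(42L)
      cw <- table(ytr)
      cw <- length(ytr) / (length(cw) * cw)
      fit <- randomForest::randomForest(
        Xtr, ytr, ntree = 100L, classwt = as.numeric(cw),
        xtest = Xval, keep.forest = FALSE
      )
      fit$test$predicted
    },
    knn = knn_vote(sq_dist(Xval, Xtr), ytr)$labels,
    nb = predict_nb(fit_nb(Xtr, ytr), Xval)$labels,
    stop("unknown model family: ", family)
  )
}

# ---- full fit (final refit on the training set) ----------------------------

fit_final_model <- function(family, Xtr, ytr) {
  if (all_constant(Xtr)) {
    return(structure(list(family = "const", fit = list(ytr = ytr)),
                     class = "tugcop_model"))
  }
  obj <- switch(family,
    svm = {
      set.seed(42L)
      cw <- table(ytr)
      cw <- length(ytr) / (length(cw) * cw)
      e1071::svm(
        Xtr, ytr, kernel = "radial", cost = 1, gamma = sk_scale_gamma(Xtr),
        class.weights = cw, scale = FALSE, probability = TRUE
      )
    },
    lr = fit_lr(Xtr, ytr),
    rf = {
      set.seed(42L)
      cw <- table(ytr)
      cw <- length(ytr) / (length(cw) * cw)
      randomForest::randomForest(Xtr, ytr, ntree = 100L,
                                 classwt = as.numeric(cw))
    },
    knn = list(Xtr = Xtr, ytr = ytr),
    nb = fit_nb(Xtr, ytr),
    stop("unknown model family: ", family)
  )
  structure(list(family = family, fit = obj), class = "tugcop_model")
}

predict_final_model <- function(model, X) {
  switch(model$family,
    const = {
      lab <- majority_labels(model$fit$ytr, nrow(X))
      list(labels = lab, score = rep(0.5, nrow(X)))
    },
    svm = {
      pred <- stats::predict(model$fit, X, probability = TRUE)
      list(labels = pred,
           score = attr(pred, "probabilities")[, "PD"])
    },
    lr = {
      pr <- predict_lr(model$fit, X)
      list(labels = factor(ifelse(pr >= 0.5, "PD", "Control"),
                           levels = GROUP_LEVELS),
           score = pr)
    },
    rf = {
      pr <- stats::predict(model$fit, X, type = "prob")[, "PD"]
      list(labels = stats::predict(model$fit, X), score = pr)
    },
    knn = knn_vote(sq_dist(X, model$fit$Xtr), model$fit$ytr),
    nb = predict_nb(model$fit, X)
  )
}
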