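# Uniform interface over the six base-classifier families.
#
# Families and hyperparameters mirror the conventional search spaces for
# this pipeline: DT (single decision tree with per-split feature
# subsampling), SVM (RBF), KNN (Minkowski), MLP (two hidden layers), RF and
# GBDT. Each family is fitted through the established engine where one
# exists (ranger, e1071, xgboost); KNN and the two-layer MLP are provided
# in-package.

#' Supported classifier families
#' @return Character vector, in the canonical order used for tie-breaking.
#' @export
classifier_families <- function() c("DT", "SVM", "KNN", "MLP", "RF", "GBDT")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

ensure_colnames <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' Fit one base classifier
#'
#' @param family One of [classifier_families()].
#' @param X Numeric feature matrix (rows = samples).
#' @param y Class labels (coerced to factor; its level order is preserved in
#'   predictions).
#' @param params Named list of hyperparameters for the family:
#'   DT `max_depth`, `max_features`; SVM `C`, `gamma`; KNN `n_neighbors`,
#'   `p`; MLP `k1`, `k2` (hidden layer sizes, plus optional `epochs`); RF
#'   and GBDT `n_estimators`, `max_depth`, `max_features`.
#' @param seed Optional seed (forwarded to the engines so fits are
#'   reproducible).
#' @param need_prob Fit so that class probabilities are available (only
#'   matters for SVM, where Platt scaling is an extra cost).
#' @return A `ks_classifier` object usable with [predict_classifier()].
#' @export
fit_classifier <- function(family, X, y, params = list(), seed = NULL,
                           need_prob = FALSE) {
  family <- match.arg(family, classifier_families())
  X <- ensure_colnames(X)
  y <- as.factor(y)
  p <- ncol(X)
  seed_int <- if (is.null(seed)) 0L else as.integer(seed)
  fit <- switch(
    family,
    DT = {
      mtry <- clamp(round((params$max_features %||% 1) * p), 1, p)
      ranger::ranger(x = X, y = y, num.trees = 1,
                     max.depth = params$max_depth %||% 0,
                     mtry = mtry, replace = FALSE, sample.fraction = 1,
                     probability = TRUE, num.threads = 1, seed = seed_int)
    },
    SVM = with_seed_if(seed, {
      # scale = FALSE: inputs are already min-max scaled, and the RBF
      # C/gamma search range assumes unscaled kernel inputs
      e1071::svm(x = X, y = y, cost = params$C %||% 1,
                 gamma = params$gamma %||% (1 / p), kernel = "radial",
                 scale = FALSE, probability = need_prob)
    }),
    KNN = list(X = X, y = y,
               k = clamp(params$n_neighbors %||% 5, 1, nrow(X)),
               p = params$p %||% 2),
    MLP = mlp_fit(X, y, k1 = params$k1 %||% 50, k2 = params$k2 %||% 25,
                  epochs = params$epochs %||% 40, seed = seed),
    RF = {
      mtry <- clamp(round((params$max_features %||% sqrt(p) / p) * p), 1, p)
      ranger::ranger(x = X, y = y,
                     num.trees = max(1, params$n_estimators %||% 100),
                     max.depth = params$max_depth %||% 0, mtry = mtry,
                     probability = TRUE, num.threads = 1, seed = seed_int)
    },
    GBDT = {
      dm <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y),
                      max_depth = params$max_depth %||% 6,
                      colsample_bytree = clamp(params$max_features %||% 1,
                                               0.1, 1),
                      eta = 0.3, tree_method = "hist", max_bin = 63,
                      nthread = 1, seed = seed_int),
        data = dm, nrounds = max(1, params$n_estimators %||% 100),
        verbose = 0)
    })
  structure(list(family = family, fit = fit, classes = levels(y),
                 params = params, xnames = colnames(X),
                 need_prob = need_prob),
            class = "ks_classifier")
}

minkowski_cross_dist <- function(A, B, p) {
  # |A_i - B_j|_p for all row pairs; feature-wise accumulation keeps memory
  # at one m x n matrix.
  D <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(ncol(A))) {
    D <- D + abs(outer(A[, j], B[, j], `-`))^p
  }
  D^(1 / p)
}

knn_vote <- function(D, ytrain, k, classes) {
  k <- min(k, ncol(D))
  t(apply(D, 1, function(d) {
    nb <- ytrain[order(d)[seq_len(k)]]
    tabulate(factor(nb, levels = classes), length(classes)) / k
  }))
}

#' Predict labels or class probabilities from a fitted classifier
#'
#' @param object A [fit_classifier()] result.
#' @param X Feature matrix with the training layout.
#' @param type `"label"` (default) or `"prob"`.
#' @return Factor of labels, or a samples x classes probability matrix.
#' @export
predict_classifier <- function(object, X, type = c("label", "prob")) {
  type <- match.arg(type)
  stopifnot(inherits(object, "ks_classifier"))
  X <- ensure_colnames(X)
  if (ncol(X) != length(object$xnames)) {
    stop("X has ", ncol(X), " columns; model was trained on ",
         length(object$xnames))
  }
  colnames(X) <- object$xnames
  classes <- object$classes
  prob <- switch(
    object$family,
    DT = ,
    RF = {
      pr <- predict(object$fit, data = X, num.threads = 1)$predictions
      pr[, match(classes, colnames(pr)), drop = FALSE]
    },
    SVM = {
      if (type == "prob") {
        if (!object$need_prob) {
          stop("SVM was fitted with need_prob = FALSE; refit to get ",
               "probabilities")
        }
        pr <- attr(predict(object$fit, X, probability = TRUE),
                   "probabilities")
        pr[, match(classes, colnames(pr)), drop = FALSE]
      } else {
        lab <- predict(object$fit, X)
        return(factor(as.character(lab), levels = classes))
      }
    },
    KNN = {
      D <- minkowski_cross_dist(X, object$fit$X, object$fit$p)
      knn_vote(D, object$fit$y, object$fit$k, classes)
    },
    MLP = mlp_prob(object$fit, X),
    GBDT = {
      pr <- predict(object$fit, xgboost::xgb.DMatrix(X))
      if (!is.matrix(pr)) {
        pr <- matrix(pr, ncol = length(classes), byrow = TRUE)
      }
      dimnames(pr) <- list(NULL, classes)
      pr
    })
  if (type == "prob") {
    colnames(prob) <- classes
    prob
  } else {
    factor(classes[max.col(prob, ties.method = "first")], levels = classes)
  }
}

#' Cross-validated misclassification rate of one parameterisation
#'
#' Fits `family` with `params` on each training fold of a fixed fold
#' assignment and returns the pooled misclassification rate on the held-out
#' folds. This is the fitness used by the hyperparameter tuner; with fixed
#' folds it is a deterministic function of the parameters.
#'
#' @param family Classifier family.
#' @param params Named hyperparameter list.
#' @param X,y Training data.
#' @param fold Integer fold assignment (e.g. from stratified folds).
#' @param seed Seed forwarded to the fits.
#' @return Misclassification rate in `[0, 1]`.
#' @export
cv_misclassification <- function(family, params, X, y, fold, seed = NULL) {
  X <- ensure_colnames(X)
  y <- as.factor(y)
  wrong <- 0L
  for (j in sort(unique(fold))) {
    hold <- which(fold == j)
    mod <- fit_classifier(family, X[-hold, , drop = FALSE], y[-hold],
                          params, seed = seed)
    pred <- predict_classifier(mod, X[hold, , drop = FALSE])
    wrong <- wrong + sum(pred != y[hold])
  }
  wrong / length(y)
}
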