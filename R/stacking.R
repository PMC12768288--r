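#' Specification of a two-layer stacking ensemble
#'
#' @param base_learners Ordered named list of base-learner descriptors, each
#'   `list(family =, params =)`. Defaults to the six families with their
#'   default parameters; in the full pipeline the params come from KOA
#'   tuning.
#' @param meta_learner Descriptor of the meta-learner (default RF).
#' @param k Stacking CV folds for the out-of-fold meta-features (default 5).
#' @param meta_feature_mode `"labels"` (default; out-of-fold label
#'   predictions, one-hot-encoded for the meta-learner) or
#'   `"probabilities"`.
#' @param seed Optional seed governing fold assignment and fits.
#' @return A `stacking_spec` object.
#' @export
stacking_spec <- function(base_learners = NULL,
                          meta_learner = list(family = "RF", params = list()),
                          k = 5,
                          meta_feature_mode = c("labels", "probabilities"),
                          seed = NULL) {
  if (is.null(base_learners)) {
    base_learners <- lapply(classifier_families(), function(f) {
      list(family = f, params = list())
    })
    names(base_learners) <- classifier_families()
  }
  if (length(base_learners) < 2) stop("need at least 2 base learners")
  if (is.null(names(base_learners))) {
    names(base_learners) <- vapply(base_learners, `[[`, "", "family")
  }
  if (k < 2) stop("k must be >= 2")
  structure(list(base_learners = base_learners, meta_learner = meta_learner,
                 k = as.integer(k),
                 meta_feature_mode = match.arg(meta_feature_mode),
                 seed = seed),
            class = "stacking_spec")
}

#' Stratified train/test split
#'
#' @param X Feature matrix.
#' @param labels Class labels (every class needs >= 2 samples).
#' @param ratio Training fraction (default 0.8, the 4:1 split).
#' @param seed Optional seed.
#' @return List with `train` and `test`, each holding `X`, `labels` and the
#'   original row indices `idx`.
#' @export
split_train_test <- function(X, labels, ratio = 0.8, seed = NULL) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  if (min(table(labels)) < 2) {
    stop("every class needs at least 2 samples to stratify")
  }
  tr_idx <- with_seed_if(seed, {
    unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, round(ratio * length(idx)))
    }))
  })
  tr_idx <- sort(tr_idx)
  te_idx <- setdiff(seq_along(labels), tr_idx)
  list(train = list(X = X[tr_idx, , drop = FALSE], labels = labels[tr_idx],
                    idx = tr_idx),
       test = list(X = X[te_idx, , drop = FALSE], labels = labels[te_idx],
                   idx = te_idx))
}

#' Out-of-fold meta-features
#'
#' For each of `k` stratified folds, every base learner is fitted on the
#' other folds and predicts the held-out fold, so each training sample gets
#' exactly one out-of-fold prediction per base learner, assembled in the
#' original sample order.
#'
#' @param base_learners Named list of descriptors (`family`, `params`).
#' @param X,y Training data.
#' @param k Number of folds.
#' @param mode `"labels"` or `"probabilities"`.
#' @param seed Optional seed (fold assignment and fits).
#' @return A `meta_features` object: `matrix` (n x t character matrix of
#'   labels, or n x t*C numeric probabilities), `fold` assignment, `mode`,
#'   `classes` and `learners`.
#' @export
out_of_fold_predictions <- function(base_learners, X, y, k = 5,
                                    mode = c("labels", "probabilities"),
                                    seed = NULL) {
  mode <- match.arg(mode)
  X <- ensure_colnames(X)
  y <- as.factor(y)
  classes <- levels(y)
  n <- length(y); t_n <- length(base_learners)
  lnames <- names(base_learners) %||%
    vapply(base_learners, `[[`, "", "family")
  fold <- stratified_folds(y, k, seed = seed)
  need_prob <- mode == "probabilities"
  if (mode == "labels") {
    M <- matrix(NA_character_, n, t_n, dimnames = list(NULL, lnames))
  } else {
    M <- matrix(NA_real_, n, t_n * length(classes),
                dimnames = list(NULL, as.vector(outer(classes, lnames,
                  function(c, l) paste(l, c, sep = ".")))))
  }
  for (j in seq_len(k)) {
    hold <- which(fold == j)
    for (b in seq_len(t_n)) {
      bl <- base_learners[[b]]
      fit_seed <- if (is.null(seed)) NULL else
        derive_seed(seed, paste0("oof-", lnames[b], "-", j))
      mod <- tryCatch(
        fit_classifier(bl$family, X[-hold, , drop = FALSE], y[-hold],
                       bl$params %||% list(), seed = fit_seed,
                       need_prob = need_prob),
        error = function(e) {
          stop("base learner '", lnames[b], "' failed to fit on fold ", j,
               ": ", conditionMessage(e))
        })
      if (mode == "labels") {
        M[hold, b] <- as.character(
          predict_classifier(mod, X[hold, , drop = FALSE]))
      } else {
        cols <- (b - 1) * length(classes) + seq_along(classes)
        M[hold, cols] <- predict_classifier(mod, X[hold, , drop = FALSE],
                                            type = "prob")
      }
    }
  }
  structure(list(matrix = M, fold = fold, mode = mode, classes = classes,
                 learners = lnames),
            class = "meta_features")
}

# Numeric encoding of meta-features for the meta-learner: label mode is
# one-hot encoded per base learner, probability mode is already numeric.
meta_encode <- function(M, mode, classes, learners) {
  if (mode == "probabilities") return(as.matrix(M))
  blocks <- lapply(seq_len(ncol(M)), function(b) {
    oh <- one_hot(factor(M[, b], levels = classes), classes)
    colnames(oh) <- paste(learners[b], classes, sep = ".")
    oh
  })
  do.call(cbind, blocks)
}

#' Fit the stacking ensemble
#'
#' Builds out-of-fold meta-features, trains the meta-learner on them against
#' the true labels, and refits every base learner on the full training set
#' for inference.
#'
#' @param spec A [stacking_spec()].
#' @param X,y Training data.
#' @return A `ks_stacked` model.
#' @export
fit_stacking <- function(spec, X, y) {
  stopifnot(inherits(spec, "stacking_spec"))
  X <- ensure_colnames(X)
  y <- as.factor(y)
  mf <- out_of_fold_predictions(spec$base_learners, X, y, k = spec$k,
                                mode = spec$meta_feature_mode,
                                seed = spec$seed)
  enc <- meta_encode(mf$matrix, mf$mode, mf$classes, mf$learners)
  meta_seed <- if (is.null(spec$seed)) NULL else
    derive_seed(spec$seed, "meta-fit")
  meta <- fit_classifier(spec$meta_learner$family, enc, y,
                         spec$meta_learner$params %||% list(),
                         seed = meta_seed, need_prob = TRUE)
  base_models <- lapply(seq_along(spec$base_learners), function(b) {
    bl <- spec$base_learners[[b]]
    fit_seed <- if (is.null(spec$seed)) NULL else
      derive_seed(spec$seed, paste0("refit-", names(spec$base_learners)[b]))
    fit_classifier(bl$family, X, y, bl$params %||% list(), seed = fit_seed,
                   need_prob = spec$meta_feature_mode == "probabilities")
  })
  names(base_models) <- names(spec$base_learners)
  structure(list(base_models = base_models, meta_model = meta, spec = spec,
                 classes = levels(y), meta_features = mf,
                 n_refit_rows = nrow(X)),
            class = "ks_stacked")
}

base_layer_predict <- function(model, X) {
  mode <- model$spec$meta_feature_mode
  classes <- model$classes
  lnames <- names(model$base_models)
  if (mode == "labels") {
    M <- vapply(model$base_models, function(m) {
      as.character(predict_classifier(m, X))
    }, character(nrow(X)))
    M <- matrix(M, nrow = nrow(X), dimnames = list(NULL, lnames))
  } else {
    M <- do.call(cbind, lapply(model$base_models, function(m) {
      predict_classifier(m, X, type = "prob")
    }))
  }
  meta_encode(M, mode, classes, lnames)
}

#' Predict from a stacking ensemble
#'
#' Base-learner predictions on `X` are encoded exactly as at training time
#' (no out-of-fold machinery at inference) and passed to the meta-learner.
#'
#' @param object A `ks_stacked` model.
#' @param newdata Feature matrix in the training layout.
#' @param type `"label"` (default) or `"prob"` (meta-learner class
#'   probabilities).
#' @param ... Unused.
#' @return Factor of labels drawn from the training label set, or a
#'   probability matrix.
#' @export
predict.ks_stacked <- function(object, newdata, type = c("label", "prob"),
                               ...) {
  type <- match.arg(type)
  enc <- base_layer_predict(object, ensure_colnames(newdata))
  predict_classifier(object$meta_model, enc, type = type)
}

#' Combinatorial meta-learner selection
#'
#' Builds the out-of-fold meta-feature matrix once from the (tuned) base
#' learners, then scores every candidate meta-learner by stratified k-fold
#' cross-validation on that matrix — a leakage-safe selection confined to
#' the training split. Ties in accuracy are broken by candidate order.
#'
#' @param candidates Named list of candidate descriptors (`family`,
#'   `params`); default the six families in canonical order.
#' @param spec A [stacking_spec()] describing the base layer.
#' @param X,y Training data.
#' @param seed Optional seed for the candidate-CV folds.
#' @return List with `report` (one row per candidate: accuracy, macro
#'   precision/recall/F1), `chosen` (descriptor), `chosen_name` and the
#'   shared `meta_features`.
#' @export
select_meta_learner <- function(candidates = NULL, spec, X, y, seed = NULL) {
  if (is.null(candidates)) {
    candidates <- lapply(classifier_families(), function(f) {
      list(family = f, params = list())
    })
    names(candidates) <- classifier_families()
  }
  if (!length(candidates)) stop("need at least one candidate")
  X <- ensure_colnames(X)
  y <- as.factor(y)
  mf <- out_of_fold_predictions(spec$base_learners, X, y, k = spec$k,
                                mode = spec$meta_feature_mode,
                                seed = spec$seed)
  enc <- meta_encode(mf$matrix, mf$mode, mf$classes, mf$learners)
  fold <- stratified_folds(y, spec$k,
                           seed = if (is.null(seed)) NULL else
                             derive_seed(seed, "meta-select"))
  rows <- lapply(names(candidates), function(nm) {
    cand <- candidates[[nm]]
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (j in sort(unique(fold))) {
      hold <- which(fold == j)
      fit_seed <- if (is.null(seed)) NULL else
        derive_seed(seed, paste0("meta-cv-", nm, "-", j))
      mod <- fit_classifier(cand$family, enc[-hold, , drop = FALSE],
                            y[-hold], cand$params %||% list(),
                            seed = fit_seed)
      pred[hold] <- predict_classifier(mod, enc[hold, , drop = FALSE])
    }
    met <- classification_metrics(confusion_matrix(y, pred, levels(y)))
    data.frame(candidate = nm, accuracy = met$accuracy,
               macro_precision = met$macro_precision,
               macro_recall = met$macro_recall, macro_f1 = met$macro_f1)
  })
  report <- do.call(rbind, rows)
  best <- which.max(report$accuracy)  # earliest max = candidate order
  list(report = report, chosen = candidates[[best]],
       chosen_name = report$candidate[best], meta_features = mf)
}
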