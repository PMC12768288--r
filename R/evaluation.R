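#' Confusion matrix
#'
#' Cross-tabulates true against predicted labels in the declared class
#' order (rows = true class, columns = predicted class).
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param classes Ordered class set; defaults to the union of observed
#'   levels. Labels outside `classes` are an error.
#' @return Integer matrix of class `ks_confusion`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  classes <- classes %||% sort(unique(c(y_true, y_pred)))
  unseen <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unseen)) {
    stop("label(s) not in the declared class set: ",
         paste(unseen, collapse = ", "))
  }
  cm <- table(factor(y_true, levels = classes),
              factor(y_pred, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(true = classes, predicted = classes))
  structure(cm, class = c("ks_confusion", class(cm)))
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is the trace over the total. Per-class precision,
#' recall and F1 are the one-vs-rest quantities TP/(TP+FP), TP/(TP+FN) and
#' their harmonic mean; macro values are unweighted class means. Classes
#' with a zero denominator get metric 0 with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `accuracy`, `per_class` (data frame), and
#'   `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty")
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning(what, " undefined (zero denominator) for class(es) ",
              paste(classes[den == 0], collapse = ", "), "; reported as 0")
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy = sum(tp) / total,
       per_class = data.frame(class = classes, precision = precision,
                              recall = recall, f1 = f1,
                              row.names = NULL),
       macro_precision = mean(precision),
       macro_recall = mean(recall),
       macro_f1 = mean(f1))
}

#' One-vs-rest ROC AUC
#'
#' For each class, the AUC of ranking that class's score column with the
#' class as positive and all others negative; ties are handled by midranks
#' (equivalent to the trapezoidal ROC area). The macro AUC is the
#' unweighted mean over classes present in `y_true`; absent classes are
#' reported as `NA` and excluded with a warning.
#'
#' @param y_true True labels.
#' @param scores Samples x classes score matrix aligned with `classes`.
#' @param classes Class order; defaults to `colnames(scores)`.
#' @return List with `per_class` (named numeric) and `macro`.
#' @export
roc_auc_ovr <- function(y_true, scores, classes = colnames(scores)) {
  scores <- as.matrix(scores)
  if (is.null(classes)) stop("classes must be given or scores must be named")
  if (ncol(scores) != length(classes)) {
    stop("scores must have one column per class")
  }
  y_true <- as.character(y_true)
  auc <- vapply(seq_along(classes), function(j) {
    pos <- y_true == classes[j]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, j])  # midranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0)
  names(auc) <- classes
  if (anyNA(auc)) {
    warning("AUC undefined for class(es) absent from y_true: ",
            paste(classes[is.na(auc)], collapse = ", "),
            "; excluded from the macro average")
  }
  list(per_class = auc, macro = mean(auc, na.rm = TRUE))
}

#' Relative improvement between two scores, in percent
#'
#' `100 * (value - reference) / reference`, reported to two decimals — the
#' convention used when quoting one model's gain over another.
#'
#' @param value New score.
#' @param reference Baseline score (> 0).
#' @return Percent improvement rounded to two decimals.
#' @export
relative_improvement <- function(value, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  round(100 * (value - reference) / reference, 2)
}

#' Full evaluation report for a set of predictions
#'
#' @param y_true,y_pred Labels.
#' @param scores Optional samples x classes probability/score matrix; when
#'   given, per-class and macro one-vs-rest AUC are included.
#' @param classes Class order (default: levels of `y_true`).
#' @return List with the confusion matrix, accuracy, per-class and macro
#'   precision/recall/F1, and (optionally) AUCs.
#' @export
evaluate_predictions <- function(y_true, y_pred, scores = NULL,
                                 classes = NULL) {
  classes <- classes %||% levels(as.factor(y_true))
  cm <- confusion_matrix(y_true, y_pred, classes)
  out <- classification_metrics(cm)
  out$confusion <- cm
  if (!is.null(scores)) {
    a <- roc_auc_ovr(y_true, scores, classes)
    out$auc_per_class <- a$per_class
    out$macro_auc <- a$macro
  }
  out
}
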