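# Independent brute-force oracles used to validate the metric code.
brute_metrics <- function(y_true, y_pred, classes) {
  acc <- mean(y_true == y_pred)
  per <- t(vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }, numeric(3)))
  list(accuracy = acc, precision = per[, 1], recall = per[, 2],
       f1 = per[, 3])
}

brute_auc <- function(y_true, score, cl) {
  pos <- which(y_true == cl)
  neg <- which(y_true != cl)
  tot <- 0
  for (i in pos) {
    tot <- tot + sum(score[i] > score[neg]) + 0.5 * sum(score[i] == score[neg])
  }
  tot / (length(pos) * length(neg))
}

test_that("confusion matrix counts match hand tallies and marginals", {
  cm <- confusion_matrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                         c("A", "B"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2,
                                   dimnames = list(true = c("A", "B"),
                                                   predicted = c("A", "B"))),
               ignore_attr = TRUE)
  # perfect predictions give a diagonal matrix of class counts
  y <- rep(c("A", "B", "C"), times = c(3, 4, 5))
  cmd <- confusion_matrix(y, y, c("A", "B", "C"))
  expect_equal(diag(unclass(cmd)), c(A = 3L, B = 4L, C = 5L))
  expect_equal(sum(cmd) - sum(diag(unclass(cmd))), 0L)
  # row sums equal true class counts for random vectors
  withr::with_seed(3, {
    for (i in 1:20) {
      yt <- sample(LETTERS[1:4], 50, TRUE)
      yp <- sample(LETTERS[1:4], 50, TRUE)
      cmr <- confusion_matrix(yt, yp, LETTERS[1:4])
      expect_equal(rowSums(cmr), table(factor(yt, LETTERS[1:4])),
                   ignore_attr = TRUE)
    }
  })
  expect_error(confusion_matrix(c("A", "Z"), c("A", "A"), c("A", "B")), "Z")
})

test_that("classification metrics follow the one-vs-rest formulas exactly", {
  cm <- confusion_matrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                         c("A", "B"))
  met <- classification_metrics(cm)
  expect_equal(met$accuracy, 0.75)
  expect_equal(met$per_class$precision[1], 1)
  expect_equal(met$per_class$recall[1], 0.5)
  expect_equal(met$per_class$f1[1], 2 / 3)
  # diagonal matrix: everything is 1
  y <- rep(c("A", "B"), each = 4)
  perfect <- classification_metrics(confusion_matrix(y, y))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  # zero-denominator class yields 0 with a warning
  cm0 <- confusion_matrix(c("A", "A"), c("A", "A"), c("A", "B"))
  expect_warning(m0 <- classification_metrics(cm0), "undefined")
  expect_equal(m0$per_class$recall[2], 0)
})

test_that("metrics agree with the brute-force oracle on random instances", {
  withr::with_seed(41, {
    for (i in 1:100) {
      C <- sample(2:6, 1)
      n <- sample(20:80, 1)
      classes <- LETTERS[1:C]
      yt <- sample(classes, n, TRUE)
      yp <- sample(classes, n, TRUE)
      met <- suppressWarnings(
        classification_metrics(confusion_matrix(yt, yp, classes)))
      ref <- brute_metrics(yt, yp, classes)
      expect_equal(met$accuracy, ref$accuracy)
      expect_equal(unname(met$per_class$precision), unname(ref$precision))
      expect_equal(unname(met$per_class$recall), unname(ref$recall))
      expect_equal(met$macro_f1, mean(ref$f1))
    }
  })
})

test_that("one-vs-rest AUC handles perfect, reversed, tied and missing cases", {
  y <- c("A", "A", "B", "B")
  s <- cbind(A = c(0.9, 0.8, 0.1, 0.2), B = c(0.1, 0.2, 0.9, 0.8))
  a <- roc_auc_ovr(y, s)
  expect_equal(unname(a$per_class), c(1, 1))
  rev <- roc_auc_ovr(y, -s)
  expect_equal(unname(rev$per_class), c(0, 0))
  # midrank tie handling matches the pairwise-count oracle
  withr::with_seed(55, {
    for (i in 1:50) {
      n <- sample(15:60, 1)
      yt <- sample(c("A", "B", "C"), n, TRUE)
      sc <- matrix(sample(seq(0, 1, 0.1), n * 3, TRUE), n, 3,
                   dimnames = list(NULL, c("A", "B", "C")))
      got <- roc_auc_ovr(yt, sc)
      for (cl in c("A", "B", "C")) {
        expect_equal(got$per_class[[cl]], brute_auc(yt, sc[, cl], cl),
                     tolerance = 1e-12)
      }
    }
  })
  # invariance under strictly monotone score transforms
  withr::with_seed(56, {
    yt <- sample(c("A", "B"), 40, TRUE)
    sc <- matrix(runif(80), 40, 2, dimnames = list(NULL, c("A", "B")))
    a1 <- roc_auc_ovr(yt, sc)
    a2 <- roc_auc_ovr(yt, exp(3 * sc))
    expect_equal(a1$per_class, a2$per_class)
  })
  # class absent from y_true: NA, excluded from macro, warned
  expect_warning(miss <- roc_auc_ovr(c("A", "A", "B"),
                                     cbind(A = c(.9, .8, .1),
                                           B = c(.1, .2, .9),
                                           C = c(0, 0, 0))), "absent")
  expect_true(is.na(miss$per_class[["C"]]))
  expect_equal(miss$macro, mean(miss$per_class[c("A", "B")]))
})

test_that("relative improvement reproduces the published comparisons", {
  expect_equal(relative_improvement(0.9071, 0.8786), 3.24)
  expect_equal(relative_improvement(0.9071, 0.8929), 1.59)
  expect_equal(relative_improvement(0.5, 0.5), 0)
  expect_error(relative_improvement(0.9, 0), "positive")
})

test_that("evaluate_predictions assembles metrics and AUC in one report", {
  withr::with_seed(60, {
    y <- factor(sample(c("A", "B", "C"), 60, TRUE))
    pr <- matrix(runif(180), 60, 3, dimnames = list(NULL, c("A", "B", "C")))
    pr <- pr / rowSums(pr)
  })
  pred <- factor(colnames(pr)[max.col(pr)], levels = levels(y))
  rep <- suppressWarnings(evaluate_predictions(y, pred, scores = pr))
  expect_true(all(c("accuracy", "macro_f1", "macro_auc", "confusion")
                  %in% names(rep)))
  expect_gte(rep$macro_auc, 0)
  expect_lte(rep$macro_auc, 1)
})
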