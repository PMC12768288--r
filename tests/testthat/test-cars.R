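test_that("EDF schedule satisfies its boundary identities and closed form", {
  for (m in c(10, 43, 700)) {
    for (N in c(5, 20, 50)) {
      s <- edf_schedule(m, N)
      expect_equal(s$ratios[1], 1, tolerance = 1e-14)
      expect_equal(m * s$ratios[N], 2, tolerance = 1e-12)
      expect_true(all(diff(s$ratios) < 0))
    }
  }
  # independent evaluation of the closed form at m = 700, N = 20, i = 9
  a <- (700 / 2)^(1 / 19)
  k <- log(700 / 2) / 19
  s <- edf_schedule(700, 20)
  expect_equal(s$ratios[9], a * exp(-k * 9), tolerance = 1e-14)
  expect_equal(round(700 * s$ratios[9]), 59)
  expect_error(edf_schedule(2, 10), "m")
  expect_error(edf_schedule(10, 1), "N")
})

test_that("SIMPLS engine agrees with an independent PLS implementation", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40 * 8), 40, 8)
    y <- matrix(rnorm(40), 40, 1)
  })
  colnames(X) <- paste0("v", 1:8); colnames(y) <- "y"
  fit <- koastack:::pls_fit(X, y, 4)
  ref <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = FALSE)
  pred_ref <- predict(ref, X)$predict[, , 4]
  pred_own <- koastack:::pls_predict(fit, X)
  expect_equal(unname(drop(pred_own)), unname(pred_ref), tolerance = 1e-10)
})

test_that("PLS feature weights are nonnegative and find a linear signal", {
  withr::with_seed(21, {
    hits <- 0L
    for (s in 1:20) {
      X <- matrix(rnorm(80 * 10), 80, 10)
      y <- 2 * X[, 1] + rnorm(80, sd = 0.05)
      w <- pls_feature_weights(X, y, pls_config(n_components = 3), seed = s)
      expect_true(all(w >= 0))
      if (which.max(w) == 1) hits <- hits + 1L
    }
    expect_gte(hits, 15)
  })
  # collinear input stays finite
  X <- matrix(rnorm(30 * 3), 30, 3)
  X <- cbind(X, X[, 1])
  w <- pls_feature_weights(X, rnorm(30), pls_config(n_components = 2),
                           seed = 1)
  expect_true(all(is.finite(w)))
})

test_that("n_components beyond feasible rank is reduced with a warning", {
  X <- matrix(rnorm(8 * 3), 8, 3)
  expect_warning(
    pls_feature_weights(X, rnorm(8), pls_config(n_components = 10,
                                                mc_sample_ratio = 1)),
    "reduced")
})

test_that("adaptive reweighted sampling honours weights, seeds and fallbacks", {
  # degenerate distribution: only the weighted feature survives
  expect_identical(ars_sample(c(0, 1, 0), n_keep = 5, seed = 1), 2L)
  # seed contract
  w <- runif(30)
  expect_identical(ars_sample(w, 20, seed = 9), ars_sample(w, 20, seed = 9))
  # all-zero weights: uniform fallback with warning
  expect_warning(ids <- ars_sample(rep(0, 10), 5, seed = 2), "uniform")
  expect_true(all(ids %in% 1:10))
  # unique-count expectation for equal weights: m(1 - (1 - 1/m)^m)
  m <- 25
  expected <- m * (1 - (1 - 1 / m)^m)
  counts <- withr::with_seed(17, {
    replicate(1000, length(unique(sample.int(m, m, replace = TRUE))))
  })
  obs <- vapply(1:1000, function(s) {
    length(ars_sample(rep(1, m), m, seed = s))
  }, 0L)
  expect_lt(abs(mean(obs) - expected), 3 * sd(counts) / sqrt(1000))
})

test_that("RMSECV is near zero for noiseless linear data and matches a brute-force oracle", {
  withr::with_seed(5, {
    X <- matrix(rnorm(30 * 5), 30, 5)
    beta <- c(1, -2, 0.5, 0, 3)
  })
  y <- drop(X %*% beta)
  cfg <- pls_config(n_components = 5, cv_folds = 5)
  expect_lt(rmsecv(X, y, cfg, seed = 1), 1e-8)

  # brute-force oracle on a noisy instance with an explicit fold vector
  y2 <- y + withr::with_seed(6, rnorm(30, sd = 0.4))
  fold <- rep(1:5, each = 6)
  cfg2 <- pls_config(n_components = 3, cv_folds = 5)
  got <- rmsecv(X, y2, cfg2, fold = fold)
  sse <- 0
  for (j in 1:5) {
    hold <- which(fold == j)
    f <- koastack:::pls_fit(X[-hold, ], matrix(y2[-hold]), 3)
    sse <- sse + sum((y2[hold] - koastack:::pls_predict(f, X[hold, ]))^2)
  }
  expect_equal(got, sqrt(sse / 30), tolerance = 1e-12)

  # pooling invariance: permuting samples together with their folds
  perm <- withr::with_seed(8, sample(30))
  expect_equal(rmsecv(X[perm, ], y2[perm], cfg2, fold = fold[perm]), got,
               tolerance = 1e-12)
})

test_that("run_cars contracts: monotone subset sizes, ARS within EDF, determinism", {
  withr::with_seed(31, {
    X <- matrix(rnorm(60 * 50), 60, 50)
    y <- rep(c("A", "B"), each = 30)
    X[y == "A", 3] <- X[y == "A", 3] + 2
    X[y == "A", 17] <- X[y == "A", 17] - 2
  })
  colnames(X) <- paste0("ch", 1:50)
  res <- run_cars(X, y, N = 6, config = pls_config(n_components = 3),
                  seed = 42)
  it <- res$iterations
  expect_true(all(diff(it$n_after_edf) <= 0))
  expect_true(all(diff(it$n_after_ars) <= 0))
  expect_true(all(it$n_after_ars <= it$n_after_edf))
  for (i in seq_along(res$sets)) {
    expect_true(all(res$sets[[i]]$ars %in% res$sets[[i]]$edf))
  }
  expect_equal(res$best_iteration, which.min(res$rmsecv_curve))
  expect_true(all(res$selected_features %in% seq_len(50)))
  expect_equal(res$selected_names,
               paste0("ch", res$selected_features))
  res2 <- run_cars(X, y, N = 6, config = pls_config(n_components = 3),
                   seed = 42)
  expect_identical(res$iterations, res2$iterations)
  expect_identical(res$selected_features, res2$selected_features)
  expect_error(run_cars(X, y, N = 1), "N")
  expect_error(run_cars(X, rep("A", 60), N = 5), "classes")
})

test_that("the final EDF retention target is two features", {
  s <- edf_schedule(50, 6)
  expect_equal(round(50 * s$ratios[6]), 2)
})

test_that("CARS report writer emits the iteration table and selected ids", {
  withr::with_seed(13, {
    X <- matrix(rnorm(40 * 20), 40, 20)
    y <- rep(c("A", "B"), each = 20)
    X[y == "B", 5] <- X[y == "B", 5] + 3
  })
  colnames(X) <- paste0("ch", 1:20)
  res <- run_cars(X, y, N = 4, config = pls_config(n_components = 2),
                  seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_cars_report(res, file.path(dir, "rep.csv"),
                             file.path(dir, "sel.json"))
  rep <- read.csv(paths["report"])
  expect_named(rep, c("iteration", "n_after_edf", "n_after_ars", "rmsecv"))
  sel <- jsonlite::read_json(paths["selected"], simplifyVector = TRUE)
  expect_equal(sel, res$selected_names)
})

test_that("reference CARS selections parse and have the published sizes", {
  wns <- jsonlite::read_json(
    system.file("extdata", "reference_selected_wavenumbers.json",
                package = "koastack"), simplifyVector = TRUE)
  expect_length(wns, 44)
  grid <- wavenumber_grid()
  expect_true(all(wns %in% grid$wavenumbers))
  feats <- jsonlite::read_json(
    system.file("extdata", "reference_selected_image_features.json",
                package = "koastack"), simplifyVector = TRUE)
  expect_length(feats, 15)
  expect_true(all(feats %in% as.character(image_feature_names())))
})
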