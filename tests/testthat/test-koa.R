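sphere_space <- function() {
  search_space(c("x", "y"), c(-5, -5), c(5, 5),
               c("continuous", "continuous"))
}

test_that("population initialisation respects bounds, seed and sun definition", {
  sp <- sphere_space()
  obj <- function(p) sum(p^2)
  st <- initialize_population(obj, sp, koa_config(seed = 7))
  expect_true(all(st$positions >= -5 & st$positions <= 5))
  expect_true(all(st$velocities == 0))
  expect_equal(st$sun_fitness, min(st$fitness))
  expect_equal(unname(st$sun), unname(st$positions[which.min(st$fitness), ]))
  st2 <- initialize_population(obj, sp, koa_config(seed = 7))
  expect_identical(st$positions, st2$positions)
  expect_error(initialize_population(obj, sp[0, ], koa_config()), "empty")
})

test_that("orbital update evaluates the published formula literally", {
  # identity case: no velocity contribution, mask all zero
  expect_equal(orbital_position_update(c(1, 2), c(0, 0), c(5, 5),
                                       F = 1, Fg = 0.4, r = 1, U = c(0, 0)),
               c(1, 2))
  # hand substitution in 1-D
  expect_equal(orbital_position_update(0, 0.5, 1, F = 1, Fg = 0.2, r = 0.3,
                                       U = 1), 1.0)
  # brute-force agreement on random 5-D instances; with F*V = 0 and U = 1
  # the step moves toward the sun iff Fg + |r| is in (0, 2)
  withr::with_seed(12, {
    for (i in 1:25) {
      x <- rnorm(5); s <- rnorm(5); v <- rnorm(5)
      F <- sample(c(-1, 1), 1); Fg <- runif(1, 0, 1.5); r <- rnorm(1)
      U <- rbinom(5, 1, 0.5)
      expect_equal(orbital_position_update(x, v, s, F, Fg, r, U),
                   x + F * v + (Fg + abs(r)) * U * (s - x))
      coef <- Fg + abs(r)
      moved <- orbital_position_update(x, 0 * v, s, F, Fg, r, rep(1, 5))
      closer <- sqrt(sum((moved - s)^2)) < sqrt(sum((x - s)^2))
      expect_equal(closer, coef > 0 && coef < 2)
    }
  })
  expect_error(orbital_position_update(1:2, 1:3, 1:2, 1, 0, 0, 1:2),
               "equal length")
})

test_that("distance-adaptive update evaluates the published formula literally", {
  # all-ones mask leaves the position unchanged
  expect_equal(distance_adaptive_update(c(1, 2), c(9, 9), c(0, 0), c(4, 4),
                                        U1 = c(1, 1), h = 3), c(1, 2))
  # hand substitution in 1-D
  expect_equal(distance_adaptive_update(0, 3, 3, x_b = 0, U1 = 0, h = 0), 2)
  # cancellation: with X_b equal to the three-point mean the h-term vanishes
  m3 <- (1 + 5 + 3) / 3
  expect_equal(distance_adaptive_update(1, 5, 3, x_b = m3, U1 = 0, h = 1),
               m3)
  expect_error(distance_adaptive_update(1:2, 1:2, 1:2, 1:3, 1:2, 1),
               "equal length")
})

test_that("elitism holds for arbitrary objectives and the constant objective", {
  sp <- sphere_space()
  withr::with_seed(2, {
    for (s in 1:5) {
      obj <- local({
        A <- rnorm(2); function(p) sum(sin(p) * A) + 0.1 * sum(p^2)
      })
      res <- koa_optimize(obj, sp, koa_config(max_iter = 15, seed = s))
      expect_true(all(diff(res$history) <= 0))
    }
  })
  res <- koa_optimize(function(p) 3.5, sp, koa_config(max_iter = 5, seed = 1))
  expect_equal(res$best_fitness, 3.5)
  expect_equal(res$history, rep(3.5, 5))
})

test_that("non-finite objective values are treated as +Inf with a warning", {
  sp <- sphere_space()
  obj <- function(p) if (p[1] > 0) NaN else sum(p^2)
  expect_warning(res <- koa_optimize(obj, sp, koa_config(max_iter = 3,
                                                         seed = 4)),
                 "non-finite")
  expect_true(is.finite(res$best_fitness))
})

test_that("hyperparameter decoding rounds integers and attaches names", {
  dt <- default_search_space("DT")
  dec <- decode_hyperparameters(c(13.4, 0.45), dt)
  expect_identical(dec$max_depth, 13L)
  expect_equal(dec$max_features, 0.45)
  mlp <- default_search_space("MLP")
  dec2 <- decode_hyperparameters(c(96.2, 74.4), mlp)
  expect_identical(dec2$k1, 96L)
  expect_identical(dec2$k2, 74L)
  # integer endpoints decode to themselves
  knn <- default_search_space("KNN")
  expect_identical(decode_hyperparameters(c(1, 5), knn),
                   list(n_neighbors = 1L, p = 5L))
  expect_error(decode_hyperparameters(c(0, 2), knn), "bounds")
})

test_that("KOA converges on the 2-D sphere and beats random search at equal budget", {
  sp <- sphere_space()
  budget_evals <- 10 * 21  # population x (init + iterations)
  koa_best <- numeric(10)
  rs_best <- numeric(10)
  for (s in 1:10) {
    koa_best[s] <- koa_optimize(function(p) sum(p^2), sp,
                                koa_config(pop_size = 10, max_iter = 20,
                                           seed = s))$best_fitness
    rs_best[s] <- withr::with_seed(s, {
      min(replicate(budget_evals, sum(runif(2, -5, 5)^2)))
    })
  }
  expect_lt(median(koa_best), median(rs_best))
  expect_lt(median(koa_best), 1e-2)
})

test_that("KOA beats equal-budget random search on the 2-D Rosenbrock valley", {
  sp <- sphere_space()
  rosen <- function(p) (1 - p[1])^2 + 100 * (p[2] - p[1]^2)^2
  budget <- 10 * 21
  ko <- vapply(1:10, function(s) {
    koa_optimize(rosen, sp, koa_config(pop_size = 10, max_iter = 20,
                                       seed = s))$best_fitness
  }, 0)
  rs <- vapply(1:10, function(s) {
    withr::with_seed(500 + s, min(replicate(budget, rosen(runif(2, -5, 5)))))
  }, 0)
  expect_lt(median(ko), median(rs))
})

test_that("tune_model is deterministic, matches a manual fitness check and beats the midpoint", {
  blobs <- make_blobs(n_per_class = 15, classes = 3, p = 6, noise = 1.2,
                      seed = 30)
  cfg <- koa_config(pop_size = 4, max_iter = 4, seed = 11)
  tm <- tune_model("DT", blobs$X, blobs$y, config = cfg, cv_folds = 3)
  tm2 <- tune_model("DT", blobs$X, blobs$y, config = cfg, cv_folds = 3)
  expect_identical(tm$best_params, tm2$best_params)
  expect_equal(tm$best_cv_error, tm2$best_cv_error)
  expect_true(all(diff(tm$history) <= 0))

  # the reported fitness equals an independent CV computation at the same
  # decoded parameters and folds
  fold <- koastack:::stratified_folds(
    blobs$y, 3, seed = koastack:::derive_seed(11, "folds-DT"))
  manual <- cv_misclassification("DT", tm$best_params, blobs$X, blobs$y,
                                 fold,
                                 seed = koastack:::derive_seed(11, "fit-DT"))
  expect_equal(tm$best_cv_error, manual)

  # tuned fitness is never worse than the space's midpoint parameters
  space <- default_search_space("DT")
  mid <- decode_hyperparameters((space$lower + space$upper) / 2, space)
  mid_err <- cv_misclassification("DT", mid, blobs$X, blobs$y, fold,
                                  seed = koastack:::derive_seed(11, "fit-DT"))
  expect_lte(tm$best_cv_error, mid_err)
  expect_error(tune_model("NOPE", blobs$X, blobs$y), "arg")
})
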