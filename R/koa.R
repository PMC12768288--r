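# Kepler optimization algorithm (KOA) for bounded mixed search spaces.
#
# The two position-update rules are the published core of the method:
#   orbital update:    X' = X + F*V + (Fg + |r|) * U * (X_S - X)
#   distance update:   X' = X*U1 + (1-U1)*M + (1-U1)*h*(M - X_b),
#                      M = (X + X_S + X_a) / 3
# Everything that generates their inputs (planet masses from fitness, the
# decaying gravity constant, eccentricities, the velocity rule, the h
# schedule, the Bernoulli masks U/U1 and the random reference planets
# X_a/X_b) is algorithm plumbing chosen here, exposed as koa_config fields
# so the mechanics are auditable and overridable:
#   - mass m_i = (worst - f_i)/(worst - best), sun mass 1;
#   - gravity Fg_i = ecc_i * mu0 * exp(-gamma_mu * t/T) * m_i / (R_i^2 + eps),
#     R_i = distance to the sun normalised by the population maximum,
#     capped at fg_cap;
#   - velocity V_i = v_scale * u * (X_a - X_b), u ~ U(-1,1)^d, so steps
#     shrink as the population contracts;
#   - h = h0 * exp(-gamma_h * t/T) * |N(0,1)| (large early: exploration;
#     small late: exploitation near the sun);
#   - the distance-adaptive rule is chosen per planet with probability
#     p_distance0 * exp(-gamma_h * t/T), tied to the same decay as h;
#   - per-planet elitist acceptance: a move is kept only if it does not
#     worsen the planet's fitness; the sun is the incumbent best ever.

#' Define a bounded mixed search space
#'
#' @param names Parameter names (unique).
#' @param lower,upper Numeric bounds, `lower < upper` elementwise.
#' @param kind `"continuous"` or `"integer"` per parameter.
#' @return A `search_space` data frame.
#' @export
search_space <- function(names, lower, upper, kind) {
  stopifnot(length(names) == length(lower),
            length(lower) == length(upper),
            length(kind) == length(names))
  if (anyDuplicated(names)) stop("parameter names must be unique")
  if (any(lower >= upper)) stop("lower bounds must be below upper bounds")
  kind <- vapply(kind, match.arg, "", choices = c("continuous", "integer"))
  structure(data.frame(name = names, lower = lower, upper = upper,
                       kind = kind, stringsAsFactors = FALSE),
            class = c("search_space", "data.frame"))
}

#' Default hyperparameter search space of a classifier family
#'
#' DT: max_depth 1..100, max_features 0.1..1; SVM: C 1..1000, gamma 0.1..1;
#' KNN: n_neighbors 1..100, p 1..5; MLP: hidden sizes k1, k2 each 10..100;
#' RF and GBDT: n_estimators 1..100, max_depth 1..100, max_features 0.1..1.
#'
#' @param family One of [classifier_families()].
#' @return A [search_space()].
#' @export
default_search_space <- function(family) {
  family <- match.arg(family, classifier_families())
  switch(family,
    DT = search_space(c("max_depth", "max_features"), c(1, 0.1), c(100, 1),
                      c("integer", "continuous")),
    SVM = search_space(c("C", "gamma"), c(1, 0.1), c(1000, 1),
                       c("continuous", "continuous")),
    KNN = search_space(c("n_neighbors", "p"), c(1, 1), c(100, 5),
                       c("integer", "integer")),
    MLP = search_space(c("k1", "k2"), c(10, 10), c(100, 100),
                       c("integer", "integer")),
    RF = ,
    GBDT = search_space(c("n_estimators", "max_depth", "max_features"),
                        c(1, 1, 0.1), c(100, 100, 1),
                        c("integer", "integer", "continuous")))
}

#' KOA configuration
#'
#' @param pop_size Planets in the population (>= 2; default 10).
#' @param max_iter Iterations (default 50).
#' @param seed Optional seed for the whole optimisation.
#' @param mu0,gamma_mu Initial gravity constant and its exponential decay
#'   rate over scaled time.
#' @param ecc_range Range the per-planet orbital eccentricities are drawn
#'   from at initialisation.
#' @param fg_cap Upper cap on the gravitational pull coefficient.
#' @param v_scale Scale of the velocity term (relative to the spread of two
#'   random planets).
#' @param u_prob,u1_prob Bernoulli rates of the binary masks in the orbital
#'   and distance-adaptive updates.
#' @param h0,gamma_h Scale and decay rate of the regulating parameter h.
#' @param p_distance0 Initial probability of choosing the distance-adaptive
#'   update (decays with the h schedule).
#' @return A `koa_config` object.
#' @export
koa_config <- function(pop_size = 10, max_iter = 50, seed = NULL,
                       mu0 = 1, gamma_mu = 3, ecc_range = c(0, 1),
                       fg_cap = 1, v_scale = 0.2, u_prob = 0.5,
                       u1_prob = 0.5, h0 = 1, gamma_h = 3,
                       p_distance0 = 0.6) {
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter), seed = seed,
                 mu0 = mu0, gamma_mu = gamma_mu, ecc_range = ecc_range,
                 fg_cap = fg_cap, v_scale = v_scale, u_prob = u_prob,
                 u1_prob = u1_prob, h0 = h0, gamma_h = gamma_h,
                 p_distance0 = p_distance0),
            class = "koa_config")
}

#' Orbital position update
#'
#' Literal evaluation of the orbital-motion rule
#' `X + F * V + (Fg + |r|) * U * (X_S - X)` (elementwise product with the
#' binary mask `U`; `Fg` scalar).
#'
#' @param position,velocity Current planet position and velocity vectors.
#' @param sun Incumbent best position.
#' @param F Direction factor (scalar, typically +/- 1).
#' @param Fg Gravitational pull (scalar).
#' @param r Random scalar; only `|r|` enters.
#' @param U Binary vector of the position's dimension.
#' @return Updated position vector.
#' @export
orbital_position_update <- function(position, velocity, sun, F, Fg, r, U) {
  d <- length(position)
  if (length(velocity) != d || length(sun) != d || length(U) != d) {
    stop("position, velocity, sun and U must have equal length")
  }
  position + F * velocity + (Fg + abs(r)) * U * (sun - position)
}

#' Distance-adaptive position update
#'
#' Literal evaluation of the sun-distance rule
#' `X * U1 + (1 - U1) * M + (1 - U1) * h * (M - X_b)` with
#' `M = (X + X_S + X_a) / 3`.
#'
#' @param position Current planet position.
#' @param sun Incumbent best position.
#' @param x_a,x_b Reference positions drawn from the population.
#' @param U1 Binary vector of the position's dimension.
#' @param h Regulating scalar (large: exploration, small: exploitation).
#' @return Updated position vector.
#' @export
distance_adaptive_update <- function(position, sun, x_a, x_b, U1, h) {
  d <- length(position)
  if (length(sun) != d || length(x_a) != d || length(x_b) != d ||
      length(U1) != d) {
    stop("position, sun, x_a, x_b and U1 must have equal length")
  }
  m3 <- (position + sun + x_a) / 3
  position * U1 + (1 - U1) * m3 + (1 - U1) * h * (m3 - x_b)
}

eval_objective <- function(objective, x) {
  f <- objective(x)
  if (!is.finite(f)) {
    warning("objective returned a non-finite value; treated as +Inf")
    f <- Inf
  }
  f
}

#' Initialise a KOA population
#'
#' Positions are uniform within bounds, velocities zero, and the sun is the
#' best initial planet.
#'
#' @param objective Function mapping a position vector to a scalar to
#'   minimise.
#' @param space A [search_space()].
#' @param config A [koa_config()]; `config$seed` (if set) makes the draw
#'   reproducible.
#' @return A `koa_state` with `positions`, `velocities`, `fitness`,
#'   `eccentricity`, `sun`, `sun_fitness` and an empty `history`.
#' @export
initialize_population <- function(objective, space, config = koa_config()) {
  if (nrow(space) == 0) stop("search space is empty")
  d <- nrow(space)
  npop <- config$pop_size
  state <- with_seed_if(config$seed, {
    pos <- sapply(seq_len(d), function(j) {
      runif(npop, space$lower[j], space$upper[j])
    })
    pos <- matrix(pos, npop, d, dimnames = list(NULL, space$name))
    ecc <- runif(npop, config$ecc_range[1], config$ecc_range[2])
    list(positions = pos, velocities = matrix(0, npop, d), ecc = ecc)
  })
  fitness <- apply(state$positions, 1, function(x) eval_objective(objective, x))
  best <- which.min(fitness)
  structure(list(positions = state$positions,
                 velocities = state$velocities,
                 fitness = fitness, eccentricity = state$ecc,
                 sun = state$positions[best, ], sun_fitness = fitness[best],
                 iteration = 0L, history = numeric(0)),
            class = "koa_state")
}

#' Run the Kepler optimization algorithm
#'
#' Minimises `objective` over the bounded space. Each iteration every planet
#' takes either an orbital step toward the sun or a distance-adaptive step,
#' is clamped to the bounds, and keeps its move only if the fitness does not
#' worsen; the sun is the best solution ever evaluated, so the best-fitness
#' history is non-increasing.
#'
#' @param objective Function position -> scalar to minimise (non-finite
#'   values are treated as +Inf with a warning).
#' @param space A [search_space()].
#' @param config A [koa_config()].
#' @return List with `best_position` (named), `best_fitness`, `history`
#'   (best fitness per iteration) and the final `state`.
#' @export
koa_optimize <- function(objective, space, config = koa_config()) {
  state <- initialize_population(objective, space, config)
  npop <- config$pop_size
  d <- nrow(space)
  TT <- config$max_iter
  run_seed <- if (is.null(config$seed)) NULL else
    derive_seed(config$seed, "koa-loop")
  history <- numeric(TT)

  step_all <- function() {
    for (t in seq_len(TT)) {
      tau <- t / TT
      mu_t <- config$mu0 * exp(-config$gamma_mu * tau)
      decay <- exp(-config$gamma_h * tau)
      fin <- state$fitness[is.finite(state$fitness)]
      worst <- if (length(fin)) max(fin) else 1
      span <- worst - state$sun_fitness
      dist_sun <- sqrt(rowSums(sweep(state$positions, 2, state$sun)^2))
      max_dist <- max(dist_sun, 1e-12)
      for (i in seq_len(npop)) {
        others <- setdiff(seq_len(npop), i)
        ab <- if (length(others) >= 2) sample(others, 2) else c(others, others)
        x <- state$positions[i, ]
        if (runif(1) < config$p_distance0 * decay) {
          U1 <- rbinom(d, 1, config$u1_prob)
          h <- config$h0 * decay * abs(rnorm(1))
          newx <- distance_adaptive_update(
            x, state$sun, state$positions[ab[1], ], state$positions[ab[2], ],
            U1, h)
        } else {
          vel <- config$v_scale * runif(d, -1, 1) *
            (state$positions[ab[1], ] - state$positions[ab[2], ])
          state$velocities[i, ] <<- vel
          mass <- if (span > 0 && is.finite(state$fitness[i])) {
            (worst - state$fitness[i]) / span
          } else if (is.finite(state$fitness[i])) 1 else 0
          Rn <- dist_sun[i] / max_dist
          Fg <- min(state$eccentricity[i] * mu_t * mass / (Rn^2 + 1e-8),
                    config$fg_cap)
          newx <- orbital_position_update(
            x, vel, state$sun, F = sign(runif(1) - 0.5), Fg = Fg,
            r = rnorm(1), U = rbinom(d, 1, config$u_prob))
        }
        newx <- clamp(newx, space$lower, space$upper)
        fnew <- eval_objective(objective, newx)
        if (fnew <= state$fitness[i]) {  # elitist planet acceptance
          state$positions[i, ] <<- newx
          state$fitness[i] <<- fnew
          if (fnew < state$sun_fitness) {
            state$sun <<- newx
            state$sun_fitness <<- fnew
          }
        }
      }
      history[t] <<- state$sun_fitness
    }
  }
  with_seed_if(run_seed, step_all())
  state$iteration <- TT
  state$history <- history
  best <- state$sun
  names(best) <- space$name
  list(best_position = best, best_fitness = state$sun_fitness,
       history = history, state = state)
}

#' Decode a position vector into named hyperparameters
#'
#' Integer-kind entries are rounded to the nearest integer and re-clamped to
#' their bounds; continuous entries pass through unchanged.
#'
#' @param position Numeric vector within the bounds of `space`.
#' @param space A [search_space()].
#' @return Named list of parameter values.
#' @export
decode_hyperparameters <- function(position, space) {
  if (length(position) != nrow(space)) {
    stop("position has length ", length(position), " but the space has ",
         nrow(space), " parameters")
  }
  tol <- 1e-9
  if (any(position < space$lower - tol) || any(position > space$upper + tol)) {
    stop("position lies outside the search-space bounds")
  }
  out <- as.list(position)
  names(out) <- space$name
  for (j in seq_len(nrow(space))) {
    if (space$kind[j] == "integer") {
      out[[j]] <- as.integer(clamp(round(position[j]),
                                   space$lower[j], space$upper[j]))
    }
  }
  out
}

param_key <- function(params) {
  paste(vapply(params, function(v) format(v, digits = 12), ""),
        collapse = "|")
}

#' Tune one classifier family with KOA
#'
#' The fitness of a position is the stratified k-fold cross-validated
#' misclassification rate of the family fitted with the decoded
#' hyperparameters; the folds are fixed for the whole tuning run, so fitness
#' is a deterministic function of position, and evaluations are cached by
#' decoded-parameter key (integer rounding makes many positions equivalent).
#' The returned model is refitted on the full training data at the best
#' parameters.
#'
#' @param family One of [classifier_families()].
#' @param X,y Training data (already preprocessed).
#' @param space Search space; defaults to [default_search_space()] for the
#'   family.
#' @param config A [koa_config()].
#' @param cv_folds Folds of the internal fitness CV (default 3).
#' @return List with `model` (a `ks_classifier` refit on all of `X`),
#'   `best_params`, `best_cv_error`, `history` and `family`.
#' @export
tune_model <- function(family, X, y, space = default_search_space(family),
                       config = koa_config(), cv_folds = 3) {
  family <- match.arg(family, classifier_families())
  X <- ensure_colnames(X)
  y <- as.factor(y)
  fold_seed <- if (is.null(config$seed)) NULL else
    derive_seed(config$seed, paste0("folds-", family))
  fold <- stratified_folds(y, cv_folds, seed = fold_seed)
  fit_seed <- if (is.null(config$seed)) NULL else
    derive_seed(config$seed, paste0("fit-", family))

  knn_cache <- NULL
  if (family == "KNN") {
    # All Minkowski exponents in the default space are integers 1..5;
    # precompute each full distance matrix once and slice per fold.
    knn_cache <- new.env(parent = emptyenv())
  }
  knn_cv <- function(params) {
    key <- paste0("p", params$p)
    if (is.null(knn_cache[[key]])) {
      knn_cache[[key]] <- minkowski_cross_dist(X, X, params$p)
    }
    D <- knn_cache[[key]]
    classes <- levels(y)
    wrong <- 0L
    for (j in sort(unique(fold))) {
      hold <- which(fold == j)
      pr <- knn_vote(D[hold, -hold, drop = FALSE], y[-hold],
                     min(params$n_neighbors, length(y) - length(hold)),
                     classes)
      pred <- classes[max.col(pr, ties.method = "first")]
      wrong <- wrong + sum(pred != as.character(y[hold]))
    }
    wrong / length(y)
  }

  cache <- new.env(parent = emptyenv())
  objective <- function(position) {
    params <- decode_hyperparameters(position, space)
    key <- param_key(params)
    if (!is.null(cache[[key]])) return(cache[[key]])
    err <- if (family == "KNN") {
      knn_cv(params)
    } else {
      cv_misclassification(family, params, X, y, fold, seed = fit_seed)
    }
    cache[[key]] <- err
    err
  }

  res <- koa_optimize(objective, space, config)
  best_params <- decode_hyperparameters(res$best_position, space)
  model <- fit_classifier(family, X, y, best_params, seed = fit_seed,
                          need_prob = TRUE)
  list(model = model, best_params = best_params,
       best_cv_error = res$best_fitness, history = res$history,
       family = family)
}
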