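#' PLS configuration for CARS
#'
#' Controls the partial least squares regression that scores feature subsets
#' inside CARS.
#'
#' @param n_components Latent components (default 10, capped by rank at fit
#'   time).
#' @param cv_folds Cross-validation folds for RMSECV (default 5).
#' @param mc_sample_ratio Fraction of samples drawn (without replacement) for
#'   each Monte-Carlo weight fit; 1.0 fits on all rows.
#' @param label_encoding `"integer"` codes classes 1..C as a single numeric
#'   response (default, the classic chemometric shortcut for class data);
#'   `"one-hot"` regresses on class indicator columns.
#' @return A `pls_config` object.
#' @export
pls_config <- function(n_components = 10, cv_folds = 5,
                       mc_sample_ratio = 0.8,
                       label_encoding = c("integer", "one-hot")) {
  if (n_components < 1) stop("n_components must be >= 1")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (mc_sample_ratio <= 0 || mc_sample_ratio > 1) {
    stop("mc_sample_ratio must be in (0, 1]")
  }
  structure(list(n_components = as.integer(n_components),
                 cv_folds = as.integer(cv_folds),
                 mc_sample_ratio = mc_sample_ratio,
                 label_encoding = match.arg(label_encoding)),
            class = "pls_config")
}

#' Exponential degradation schedule for CARS
#'
#' The fraction of features retained at sampling run `i` is
#' `r_i = a * exp(-k * i)` with `a = (m/2)^(1/(N-1))` and
#' `k = ln(m/2)/(N-1)`, so that the first run keeps all `m` features
#' (`r_1 = 1`) and the last keeps exactly two (`r_N = 2/m`).
#'
#' @param m Total feature count (>= 3).
#' @param N Number of sampling runs (>= 2).
#' @return An `edf_schedule` with fields `m`, `N`, `a`, `k` and the vector
#'   `ratios`.
#' @export
edf_schedule <- function(m, N) {
  if (m < 3) stop("m must be >= 3")
  if (N < 2) stop("N must be >= 2")
  a <- (m / 2)^(1 / (N - 1))
  k <- log(m / 2) / (N - 1)
  structure(list(m = as.integer(m), N = as.integer(N), a = a, k = k,
                 ratios = a * exp(-k * seq_len(N))),
            class = "edf_schedule")
}

#' PLS-coefficient feature weights
#'
#' Fits a PLS regression on a Monte-Carlo row subsample and returns the
#' absolute regression coefficient of each feature (summed across response
#' columns under one-hot encoding). These weights drive both the
#' competitive elimination and the adaptive reweighted sampling in CARS.
#'
#' @param X Matrix restricted to the currently retained features.
#' @param y_encoded Numeric response (vector or matrix), e.g. from integer
#'   label coding.
#' @param config A [pls_config()].
#' @param seed Optional seed for the row subsample.
#' @return Nonnegative weight per column of `X`.
#' @export
pls_feature_weights <- function(X, y_encoded, config = pls_config(),
                                seed = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(y_encoded)
  n <- nrow(X)
  rows <- with_seed_if(seed, {
    sample(n, max(2L, round(config$mc_sample_ratio * n)))
  })
  feasible <- min(length(rows) - 1L, ncol(X))
  ncomp <- config$n_components
  if (ncomp > feasible) {
    warning("n_components reduced from ", ncomp, " to ", feasible,
            " (limited by subsample rank)")
    ncomp <- feasible
  }
  fit <- pls_fit(X[rows, , drop = FALSE], Y[rows, , drop = FALSE], ncomp)
  rowSums(abs(fit$coef))
}

#' Adaptive reweighted sampling
#'
#' Draws `n_keep` features with replacement, with probability proportional
#' to weight, and returns the unique drawn ids (so the returned set can be
#' smaller than `n_keep`). Features of zero weight are never drawn unless
#' all weights are zero, in which case sampling falls back to uniform with
#' a warning.
#'
#' @param weights Nonnegative feature weights.
#' @param n_keep Number of draws.
#' @param seed Optional seed.
#' @return Sorted integer vector of retained feature positions (indices into
#'   `weights`).
#' @export
ars_sample <- function(weights, n_keep, seed = NULL) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (n_keep < 1) stop("n_keep must be >= 1")
  prob <- weights
  if (sum(prob) <= 0) {
    warning("all feature weights are zero; falling back to uniform sampling")
    prob <- rep(1, length(weights))
  }
  with_seed_if(seed, {
    sort(unique(sample.int(length(weights), n_keep, replace = TRUE,
                           prob = prob)))
  })
}

#' Cross-validated RMSE of a PLS regression
#'
#' K-fold cross-validation of a PLS fit on the given feature subset; squared
#' prediction errors are pooled over all folds (and response columns) before
#' the root is taken.
#'
#' @param X_subset Matrix restricted to a candidate feature subset.
#' @param y_encoded Numeric response.
#' @param config A [pls_config()].
#' @param seed Optional seed for the fold assignment.
#' @param fold Optional explicit fold assignment (integer vector in
#'   `1..cv_folds`, one entry per sample); overrides the random assignment.
#' @return The pooled root mean squared cross-validation error.
#' @export
rmsecv <- function(X_subset, y_encoded, config = pls_config(), seed = NULL,
                   fold = NULL) {
  X <- as.matrix(X_subset)
  Y <- as.matrix(y_encoded)
  n <- nrow(X)
  k <- config$cv_folds
  if (k < 2) stop("cv_folds must be >= 2")
  if (is.null(fold)) {
    fold <- with_seed_if(seed, rep_len(sample(seq_len(k)), n)[sample(n)])
    # rep_len + shuffle gives near-equal fold sizes in random order
  }
  sse <- 0; m <- 0L
  for (j in seq_len(k)) {
    hold <- which(fold == j)
    if (!length(hold)) next
    ncomp <- min(config$n_components, n - length(hold) - 1L, ncol(X))
    fit <- pls_fit(X[-hold, , drop = FALSE], Y[-hold, , drop = FALSE],
                   max(1L, ncomp))
    err <- Y[hold, , drop = FALSE] - pls_predict(fit, X[hold, , drop = FALSE])
    sse <- sse + sum(err^2)
    m <- m + length(err)
  }
  sqrt(sse / m)
}

#' Run CARS feature selection
#'
#' Competitive adaptive reweighted sampling: for `i = 1..N`, fit PLS weights
#' on a Monte-Carlo row subsample of the currently retained features, keep
#' the top `round(r_i * m)` features by weight (competitive elimination under
#' the exponential degradation schedule), run adaptive reweighted sampling
#' within them, and record the RMSECV of the surviving subset on the full
#' data. The subset with the lowest RMSECV (earliest on ties) is selected.
#'
#' @param X Feature matrix (samples x features), finite.
#' @param labels Class labels (>= 2 classes).
#' @param N Number of sampling runs (default 20).
#' @param config A [pls_config()].
#' @param seed Optional integer seed; fixed seed makes the run
#'   deterministic.
#' @return A `cars_result`: list with `iterations` (data frame: iteration,
#'   n_after_edf, n_after_ars, rmsecv), `sets` (per-iteration EDF/ARS id
#'   sets), `best_iteration`, `selected_features` (column indices),
#'   `selected_names`, `rmsecv_curve` and the `schedule`.
#' @export
run_cars <- function(X, labels, N = 20, config = pls_config(), seed = NULL) {
  X <- assert_finite_matrix(X, "X")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("labels must contain at least 2 classes")
  if (N < 2) stop("N must be >= 2")
  m <- ncol(X)
  sched <- edf_schedule(m, N)
  Y <- encode_labels(labels, config$label_encoding)
  cfg_for <- function(n_feat, n_rows) {
    cfg <- config
    cfg$n_components <- max(1L, min(config$n_components, n_feat,
                                    n_rows - 1L))
    cfg
  }

  retained <- seq_len(m)
  sets <- list()
  rows_out <- list()
  stopped_early <- FALSE
  for (i in seq_len(N)) {
    if (length(retained) < 2) {
      stopped_early <- TRUE
      break
    }
    seed_i <- if (is.null(seed)) NULL else derive_seed(seed, paste0("iter", i))
    sub_rows <- max(2L, round(config$mc_sample_ratio * nrow(X)))
    cfg <- cfg_for(length(retained), sub_rows)
    res_i <- with_seed_if(seed_i, {
      w <- pls_feature_weights(X[, retained, drop = FALSE], Y, cfg)
      n_edf <- min(max(2L, round(sched$ratios[i] * m)), length(retained))
      keep <- order(w, decreasing = TRUE)[seq_len(n_edf)]
      edf_set <- sort(retained[keep])
      w_edf <- w[match(edf_set, retained)]
      ars_local <- ars_sample(w_edf, n_keep = n_edf)
      ars_set <- edf_set[ars_local]
      cfg2 <- cfg_for(length(ars_set), nrow(X))
      err <- rmsecv(X[, ars_set, drop = FALSE], Y, cfg2)
      list(edf = edf_set, ars = ars_set, rmsecv = err)
    })
    sets[[i]] <- res_i
    rows_out[[i]] <- data.frame(iteration = i,
                                n_after_edf = length(res_i$edf),
                                n_after_ars = length(res_i$ars),
                                rmsecv = res_i$rmsecv)
    retained <- res_i$ars
  }
  if (!length(sets)) stop("CARS performed no iterations")
  iterations <- do.call(rbind, rows_out)
  curve <- iterations$rmsecv
  best <- which.min(curve)  # earliest minimum on ties
  selected <- sets[[best]]$ars
  structure(
    list(iterations = iterations, sets = sets, best_iteration = best,
         selected_features = selected,
         selected_names = colnames(X)[selected],
         rmsecv_curve = curve, schedule = sched,
         stopped_early = stopped_early),
    class = "cars_result")
}

#' Write the per-iteration CARS report and selected ids
#'
#' Writes `report_csv` (iteration, n_after_edf, n_after_ars, rmsecv) and, if
#' `selected_json` is given, the selected feature identifiers as a JSON list
#' (wavenumbers for spectra, feature names for image tables).
#'
#' @param result A [run_cars()] result.
#' @param report_csv Path for the iteration report CSV.
#' @param selected_json Optional path for the selected-identifier JSON.
#' @param ids Identifiers to write, defaulting to the selected column names
#'   (falling back to indices when unnamed).
#' @return Invisibly, the paths written.
#' @export
write_cars_report <- function(result, report_csv, selected_json = NULL,
                              ids = NULL) {
  stopifnot(inherits(result, "cars_result"))
  write.csv(result$iterations, report_csv, row.names = FALSE)
  if (!is.null(selected_json)) {
    ids <- ids %||% (result$selected_names %||% result$selected_features)
    jsonlite::write_json(ids, selected_json, digits = NA)
  }
  invisible(c(report = report_csv, selected = selected_json))
}
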