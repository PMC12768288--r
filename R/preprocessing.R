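#' Savitzky-Golay filter parameters
#'
#' @param window Odd window length in channels (default 15).
#' @param polyorder Polynomial order (default 3); must be smaller than
#'   `window`.
#' @return An `sg_params` object.
#' @export
sg_params <- function(window = 15, polyorder = 3) {
  if (window %% 2 == 0) stop("window must be odd")
  if (polyorder >= window) stop("window must exceed polyorder")
  if (polyorder < 0) stop("polyorder must be >= 0")
  structure(list(window = as.integer(window),
                 polyorder = as.integer(polyorder)),
            class = "sg_params")
}

#' Savitzky-Golay smoothing of a spectrum table
#'
#' Applies a Savitzky-Golay filter row-wise (per spectrum) via
#' [signal::sgolayfilt()]. Edges are handled by the filter's built-in local
#' polynomial fits, i.e. polynomial extrapolation rather than padding.
#' Polynomials of degree at most `polyorder` are fixed points of the filter,
#' so smooth band shapes are preserved while high-frequency noise is
#' attenuated. The filter is linear in the input.
#'
#' @param table A `spectrum_table` (or a bare numeric matrix, rows =
#'   spectra).
#' @param params An [sg_params()] (default window 15, polyorder 3).
#' @return Object of the same shape with smoothed intensities; grid and
#'   labels are unchanged.
#' @export
savitzky_golay_smooth <- function(table, params = sg_params()) {
  stopifnot(inherits(params, "sg_params"))
  X <- if (inherits(table, "spectrum_table")) table$intensities else
    as.matrix(table)
  if (ncol(X) < params$window) {
    stop("table has ", ncol(X), " channels; window of ", params$window,
         " does not fit")
  }
  sm <- t(apply(X, 1, signal::sgolayfilt,
                p = params$polyorder, n = params$window))
  dimnames(sm) <- dimnames(X)
  if (inherits(table, "spectrum_table")) {
    table$intensities <- sm
    table
  } else {
    sm
  }
}

#' Fit per-feature min-max statistics
#'
#' Records column minima and maxima of a training matrix. Constant columns
#' (min equal to max) are permitted and flagged; [apply_min_max()] maps them
#' to zero.
#'
#' @param X Numeric matrix or data frame (rows = samples).
#' @return A `min_max_stats` object with `min`, `max`, `constant` and the
#'   feature names.
#' @export
fit_min_max <- function(X) {
  X <- assert_finite_matrix(X, "X")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  structure(list(min = mins, max = maxs,
                 constant = maxs <= mins,
                 features = colnames(X)),
            class = "min_max_stats")
}

#' Apply min-max scaling with previously fitted statistics
#'
#' Transforms each column as `(x - min) / (max - min)` using training-set
#' statistics. Values outside the training range are kept (they may fall
#' outside `[0, 1]`); constant training columns map to 0.
#'
#' @param X Matrix to transform; columns must match the fitted statistics.
#' @param stats A [fit_min_max()] result.
#' @return Scaled matrix of the same dimensions.
#' @export
apply_min_max <- function(X, stats) {
  stopifnot(inherits(stats, "min_max_stats"))
  X <- as.matrix(X)
  if (ncol(X) != length(stats$min)) {
    stop("X has ", ncol(X), " columns but stats describe ",
         length(stats$min), " features")
  }
  if (!is.null(stats$features) && !is.null(colnames(X)) &&
      !identical(as.character(colnames(X)),
                 as.character(stats$features))) {
    stop("column names of X do not match the fitted features")
  }
  rng <- stats$max - stats$min
  rng[stats$constant] <- 1  # constant columns: numerator is 0, map to 0
  out <- sweep(sweep(X, 2, stats$min, `-`), 2, rng, `/`)
  out[, stats$constant] <- 0
  out
}

#' Serialise min-max statistics to JSON (for reproducible scoring)
#' @param stats A `min_max_stats` object.
#' @param path File to write.
#' @return Invisibly, `path`.
#' @export
write_min_max_json <- function(stats, path) {
  jsonlite::write_json(
    list(min = unname(stats$min), max = unname(stats$max),
         features = stats$features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
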