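#' Wavenumber grid for Raman spectra
#'
#' Defines the spectral axis as a half-open interval `[start, stop)` sampled
#' every `step` reciprocal centimetres. The default grid, 400 to 1800 cm^-1
#' at 2 cm^-1, has exactly 700 channels (400, 402, ..., 1798).
#'
#' @param start First wavenumber (cm^-1), included.
#' @param stop End of the axis (cm^-1), excluded.
#' @param step Channel spacing (cm^-1), must be positive.
#' @return An object of class `wavenumber_grid` with fields `start`, `stop`,
#'   `step`, `n_channels` and the vector of `wavenumbers`.
#' @examples
#' g <- wavenumber_grid()
#' g$n_channels  # 700
#' @export
wavenumber_grid <- function(start = 400, stop = 1800, step = 2) {
  if (step <= 0) stop("step must be positive")
  if (stop <= start) stop("stop must exceed start")
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-9) stop("(stop - start) must be a multiple of step")
  wn <- seq(start, stop - step, by = step)
  structure(
    list(start = start, stop = stop, step = step,
         n_channels = as.integer(round(n)), wavenumbers = wn),
    class = "wavenumber_grid"
  )
}

#' Canonical image-feature names
#'
#' Returns the 43 default image-derived feature names in their three blocks:
#' 18 geometric, 7 texture and 18 colour descriptors (means and variances in
#' RGB, HSV and LAB colour spaces).
#'
#' @return Character vector of length 43 with a `blocks` attribute giving the
#'   block of each entry.
#' @export
image_feature_names <- function() {
  geometric <- c(
    "perimeter", "area", "long axis length", "short axis length",
    "aspect ratio", "eccentricity", "roundness", "rectangularity",
    "compactness", "convex area", "convex perimeter", "solidity",
    "equivalent diameter", "extent", "min feret diameter",
    "max feret diameter", "perimeter-area ratio", "form factor")
  texture <- c(
    "grey scale mean", "grey scale variance",
    "grey scale variance product function", "energy function",
    "entropy function", "contrast function", "vollath function")
  colour <- c(
    "R-mean in RGB space", "G-mean in RGB space", "B-mean in RGB space",
    "R-variance in RGB space", "G-variance in RGB space",
    "B-variance in RGB space",
    "H-mean in HSV space", "S-mean in HSV space", "V-mean in HSV space",
    "H-variance in HSV space", "S-variance in HSV space",
    "V-variance in HSV space",
    "L-mean in LAB space", "A-mean in LAB space", "B-mean in LAB space",
    "L-variance in LAB space", "A-variance in LAB space",
    "B-variance in LAB space")
  nm <- c(geometric, texture, colour)
  attr(nm, "blocks") <- rep(c("geometric", "texture", "colour"),
                            c(length(geometric), length(texture),
                              length(colour)))
  nm
}

# Baseline magnitudes for the 43 image features, on instrument-realistic
# heterogeneous scales (pixels, pixel^2, 0-255 intensities, unit ratios) so
# that min-max scaling is a meaningful step.
default_image_base <- function() {
  c(180, 2400, 62, 48, 1.3, 0.62, 0.85, 0.72, 0.88, 2450, 175, 0.97,
    55, 0.78, 47, 63, 0.075, 0.9,
    128, 220, 45, 0.35, 4.2, 12, 60,
    92, 140, 88, 160, 150, 140,
    0.32, 0.45, 0.55, 0.01, 0.02, 0.015,
    52, -8, 21, 30, 6, 9)
}

# Fixed class-effect pattern (direction of each class's shift on the
# informative image features); depends only on the class count, never on the
# user's seed, so the study conditions are stable across runs.
image_effect_pattern <- function(n_classes, n_informative) {
  withr::with_seed(derive_seed(8675309L, "image-pattern"), {
    matrix(sample(c(-1, -0.5, 0.5, 1), n_classes * n_informative,
                  replace = TRUE),
           n_classes, n_informative)
  })
}

#' Specification of a synthetic multimodal seed dataset
#'
#' Bundles every knob of the generator: class layout, per-class Gaussian
#' Raman peaks on a baseline with additive noise, and class-dependent
#' multivariate-normal image-feature blocks. The defaults emulate the study
#' conditions the pipeline targets: 7 varieties x 100 seeds, 700 spectral
#' channels, 43 image features (18 geometric / 7 texture / 18 colour).
#'
#' Spectral signal structure: a set of `shared_peaks` common to all classes
#' (the conserved biochemical bands) plus `class_peaks`, a per-class table of
#' peaks whose presence/height differs between classes. Channels lying within
#' 2.5 peak widths of any class-specific peak are recorded as
#' `informative_channel_ids` so selection methods can be scored against
#' ground truth.
#'
#' @param n_classes Number of seed varieties.
#' @param n_per_class Samples per variety.
#' @param grid A [wavenumber_grid()].
#' @param shared_peaks Data frame with columns `center`, `height`, `width`
#'   (Gaussian sd, cm^-1) present in every class.
#' @param class_peaks List (length `n_classes`) of data frames in the same
#'   layout, one per class.
#' @param baseline Either a single constant intensity or a numeric vector of
#'   polynomial coefficients evaluated over the scaled axis in `[0, 1]`.
#' @param noise_sd Standard deviation of the additive iid Gaussian noise.
#' @param gain_sd Standard deviation of the per-sample multiplicative
#'   intensity gain (mean 1), emulating excitation-power fluctuation
#'   between acquisitions; 0 disables it.
#' @param band_height_sd Log-scale standard deviation of per-sample,
#'   per-band height factors (seed-to-seed biochemical heterogeneity);
#'   the variation is correlated across a band's channels, so it cannot be
#'   averaged away within a band. 0 disables it.
#' @param image_class_means `n_classes` x 43 matrix of image-feature means.
#' @param image_cov 43 x 43 positive semidefinite covariance shared by all
#'   classes.
#' @param image_feature_names Feature names; default [image_feature_names()].
#' @param class_effect Relative magnitude of the class shift applied to the
#'   informative image features when `image_class_means` is not supplied.
#' @param seed Integer seed making the generated tables reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 7, n_per_class = 100,
                           grid = wavenumber_grid(),
                           shared_peaks = NULL, class_peaks = NULL,
                           baseline = 0.05, noise_sd = 0.11, gain_sd = 0.09,
                           band_height_sd = 0.3,
                           image_class_means = NULL, image_cov = NULL,
                           image_feature_names = koastack::image_feature_names(),
                           class_effect = 0.04,
                           seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (n_classes < 1) stop("n_classes must be >= 1")
  classes <- make.unique(rep(LETTERS, length.out = n_classes), sep = "")

  if (is.null(shared_peaks)) {
    shared_peaks <- data.frame(
      center = c(478, 578, 866, 942, 1082, 1126, 1262, 1340, 1458, 1656),
      height = c(1.0, 0.5, 0.9, 1.1, 0.7, 0.6, 0.8, 0.65, 0.95, 0.85),
      width  = c(12, 10, 14, 11, 10, 9, 13, 10, 12, 14))
  }
  if (is.null(class_peaks)) {
    # Pool of candidate discriminating bands; each class expresses four of
    # them, offset through the pool so neighbouring classes overlap partially.
    pool <- data.frame(
      center = c(486, 504, 616, 640, 672, 684, 788, 878, 924, 934, 968,
                 990, 1012, 1140, 1150, 1338, 1352, 1444, 1484, 1500,
                 1506, 1518, 1590, 1714, 1722, 1732, 1770),
      width = 9)
    class_peaks <- lapply(seq_len(n_classes), function(cl) {
      # stride 1 through the pool: neighbouring classes share three of
      # their four bands, so varieties are told apart by one or two bands
      # plus small height differences -- adjacent varieties are genuinely
      # confusable, like real cultivar panels
      take <- ((cl - 1L) + 0:3) %% nrow(pool) + 1L
      data.frame(center = pool$center[take],
                 height = 0.24 + 0.03 * ((cl + 0:3) %% 3),
                 width = pool$width[take])
    })
  }
  if (length(class_peaks) != n_classes) {
    stop("class_peaks must have one entry per class")
  }

  n_feat <- length(image_feature_names)
  if (is.null(image_class_means)) {
    base <- default_image_base()
    if (n_feat != length(base)) {
      stop("default image means are defined for the 43 canonical features; ",
           "supply image_class_means for a custom feature set")
    }
    informative <- c(1, 2, 3, 4, 22, 25, 26, 27, 29, 32, 34, 37, 38, 39, 42)
    pat <- image_effect_pattern(n_classes, length(informative))
    image_class_means <- matrix(rep(base, each = n_classes),
                                n_classes, n_feat)
    for (j in seq_along(informative)) {
      f <- informative[j]
      image_class_means[, f] <- base[f] * (1 + class_effect * pat[, j])
    }
  }
  image_class_means <- as.matrix(image_class_means)
  if (!all(dim(image_class_means) == c(n_classes, n_feat))) {
    stop("image_class_means must be ", n_classes, " x ", n_feat)
  }
  if (is.null(image_cov)) {
    sds <- 0.06 * abs(default_image_base()[seq_len(n_feat)]) + 1e-3
    image_cov <- diag(sds^2, n_feat)
  }
  image_cov <- as.matrix(image_cov)
  if (!isSymmetric(unname(image_cov), tol = 1e-8)) {
    stop("image_cov must be symmetric")
  }

  # Ground-truth informative channels: support of any class-specific peak.
  wn <- grid$wavenumbers
  informative_channel_ids <- sort(unique(unlist(lapply(class_peaks, function(pk) {
    unlist(lapply(seq_len(nrow(pk)), function(i) {
      which(abs(wn - pk$center[i]) <= 2.5 * pk$width[i])
    }))
  }))))

  structure(
    list(n_classes = n_classes, n_per_class = n_per_class, classes = classes,
         grid = grid, shared_peaks = shared_peaks, class_peaks = class_peaks,
         baseline = baseline, noise_sd = noise_sd, gain_sd = gain_sd,
         band_height_sd = band_height_sd,
         image_class_means = image_class_means, image_cov = image_cov,
         image_feature_names = image_feature_names,
         informative_channel_ids = informative_channel_ids,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

gaussian_peak_sum <- function(wn, peaks) {
  out <- numeric(length(wn))
  for (i in seq_len(nrow(peaks))) {
    out <- out + peaks$height[i] *
      exp(-0.5 * ((wn - peaks$center[i]) / peaks$width[i])^2)
  }
  out
}

check_centers_on_grid <- function(peaks, grid) {
  for (ctr in peaks$center) {
    hit <- any(abs(grid$wavenumbers - ctr) < 1e-9)
    if (!hit) stop("peak center ", ctr, " cm^-1 is not on the wavenumber grid")
  }
}

#' Generate a synthetic Raman spectrum table
#'
#' Each sample is `baseline + shared peaks + its class's peaks + iid
#' Gaussian noise`. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param grid Wavenumber grid; defaults to the grid stored in `spec`.
#' @return A `spectrum_table`: list with `intensities` (samples x channels,
#'   columns named `wn_XXXX`), `grid` and `labels`.
#' @export
generate_spectra <- function(spec, grid = spec$grid) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_per_class < 1) stop("n_per_class must be >= 1")
  check_centers_on_grid(spec$shared_peaks, grid)
  for (pk in spec$class_peaks) check_centers_on_grid(pk, grid)

  wn <- grid$wavenumbers
  base <- if (length(spec$baseline) == 1L) {
    rep(spec$baseline, length(wn))
  } else {
    x <- (wn - grid$start) / (grid$stop - grid$start)
    drop(outer(x, seq_along(spec$baseline) - 1, `^`) %*% spec$baseline)
  }
  n <- spec$n_classes * spec$n_per_class
  labels <- factor(rep(spec$classes, each = spec$n_per_class),
                   levels = spec$classes)
  bh_sd <- spec$band_height_sd %||% 0
  intensities <- with_seed_if(derive_seed(spec$seed, "spectra"), {
    out <- matrix(0, n, length(wn))
    for (cl in seq_len(spec$n_classes)) {
      rows <- which(as.integer(labels) == cl)
      peaks <- rbind(spec$shared_peaks, spec$class_peaks[[cl]])
      # one profile row per band: per-sample height factors then act on
      # whole bands, keeping within-band channels correlated
      P <- t(vapply(seq_len(nrow(peaks)), function(i) {
        peaks$height[i] * exp(-0.5 * ((wn - peaks$center[i]) /
                                        peaks$width[i])^2)
      }, numeric(length(wn))))
      f <- matrix(exp(rnorm(length(rows) * nrow(peaks), sd = bh_sd)),
                  length(rows), nrow(peaks))
      out[rows, ] <- sweep(f %*% P, 2, base, `+`)
    }
    gain <- 1 + rnorm(n, sd = spec$gain_sd %||% 0)
    out * gain +
      matrix(rnorm(n * length(wn), sd = spec$noise_sd), n, length(wn))
  })
  colnames(intensities) <- sprintf("wn_%04d", wn)
  structure(list(intensities = intensities, grid = grid, labels = labels),
            class = "spectrum_table")
}

# Draw from N(mean, cov) via symmetric eigendecomposition; tolerates PSD
# (including identically zero) covariances and rejects indefinite ones.
mvn_draw <- function(n, mean, cov, tol = 1e-8) {
  d <- length(mean)
  ei <- eigen(cov, symmetric = TRUE)
  if (any(ei$values < -tol * max(abs(ei$values), 1))) {
    stop("image_cov is not positive semidefinite")
  }
  rt <- ei$vectors %*% (sqrt(pmax(ei$values, 0)) * t(ei$vectors))
  z <- matrix(rnorm(n * d), n, d)
  sweep(z %*% rt, 2, mean, `+`)
}

#' Generate a synthetic image-feature table
#'
#' Rows are drawn from class-specific multivariate normal distributions with
#' shared covariance `spec$image_cov`.
#'
#' @param spec A [synthetic_spec()].
#' @return An `image_feature_table`: list with `values` (samples x features),
#'   `feature_names` and `labels`.
#' @export
generate_image_features <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_feat <- length(spec$image_feature_names)
  labels <- factor(rep(spec$classes, each = spec$n_per_class),
                   levels = spec$classes)
  values <- with_seed_if(derive_seed(spec$seed, "image"), {
    out <- matrix(0, length(labels), n_feat)
    for (cl in seq_len(spec$n_classes)) {
      rows <- which(as.integer(labels) == cl)
      out[rows, ] <- mvn_draw(length(rows), spec$image_class_means[cl, ],
                              spec$image_cov)
    }
    out
  })
  colnames(values) <- as.character(spec$image_feature_names)
  structure(list(values = values, feature_names = spec$image_feature_names,
                 labels = labels),
            class = "image_feature_table")
}

#' Generate an aligned multimodal dataset
#'
#' Produces the spectral and image-feature tables with identical sample order
#' and labels. With the default spec this is 7 classes x 100 samples.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `spectra` (a `spectrum_table`), `image` (an
#'   `image_feature_table`) and `labels`.
#' @export
generate_multimodal <- function(spec) {
  spectra <- generate_spectra(spec)
  image <- generate_image_features(spec)
  stopifnot(identical(spectra$labels, image$labels))
  list(spectra = spectra, image = image, labels = spectra$labels)
}

#' Write a multimodal dataset to CSV plus a JSON sidecar
#'
#' Writes `spectra.csv` (label column + one `wn_XXXX` column per channel),
#' `image_features.csv` (label column + the named features) and
#' `dataset.json` recording the generator settings, the seed and the
#' ground-truth informative channel ids for recovery experiments.
#'
#' @param dataset Result of [generate_multimodal()].
#' @param dir Output directory (created if needed).
#' @param spec The generating [synthetic_spec()], stored in the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_multimodal_csv <- function(dataset, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- file.path(dir, "spectra.csv")
  im <- file.path(dir, "image_features.csv")
  js <- file.path(dir, "dataset.json")
  write.csv(data.frame(label = dataset$spectra$labels,
                       dataset$spectra$intensities, check.names = FALSE),
            sp, row.names = FALSE)
  write.csv(data.frame(label = dataset$image$labels,
                       dataset$image$values, check.names = FALSE),
            im, row.names = FALSE)
  side <- list(
    n_samples = length(dataset$labels),
    classes = levels(dataset$labels),
    n_channels = dataset$spectra$grid$n_channels,
    image_features = dataset$image$feature_names)
  if (!is.null(spec)) {
    side$seed <- spec$seed
    side$informative_channel_ids <- spec$informative_channel_ids
    side$noise_sd <- spec$noise_sd
  }
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA)
  invisible(c(spectra = sp, image = im, sidecar = js))
}

#' Read a spectrum table written by [write_multimodal_csv()]
#' @param path CSV path with a `label` column and `wn_XXXX` columns.
#' @return A `spectrum_table`.
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("spectra CSV must have a 'label' column")
  wn_cols <- grep("^wn_", names(df), value = TRUE)
  wn <- as.numeric(sub("^wn_", "", wn_cols))
  step <- unique(round(diff(wn), 9))
  if (length(step) != 1) stop("spectra CSV wavenumbers are not evenly spaced")
  grid <- wavenumber_grid(min(wn), max(wn) + step, step)
  intens <- as.matrix(df[wn_cols])
  structure(list(intensities = intens, grid = grid,
                 labels = factor(df$label)),
            class = "spectrum_table")
}

#' Read an image-feature table written by [write_multimodal_csv()]
#' @param path CSV path with a `label` column and one column per feature.
#' @return An `image_feature_table`.
#' @export
read_image_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("image CSV must have a 'label' column")
  feat <- setdiff(names(df), "label")
  structure(list(values = as.matrix(df[feat]), feature_names = feat,
                 labels = factor(df$label)),
            class = "image_feature_table")
}
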