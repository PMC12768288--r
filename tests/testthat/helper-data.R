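# Shared fixtures, built in code.

# Small, well-separated multimodal problem for classifier and stacking
# tests: `classes` Gaussian blobs in `p` dimensions.
make_blobs <- function(n_per_class = 20, classes = 3, p = 8, sep = 4,
                       noise = 0.5, seed = 42) {
  withr::with_seed(seed, {
    y <- factor(rep(LETTERS[seq_len(classes)], each = n_per_class))
    mu <- matrix(rnorm(classes * p, sd = sep / 2), classes, p)
    X <- mu[as.integer(y), ] + matrix(rnorm(length(y) * p, sd = noise),
                                      length(y), p)
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X, y = y)
  })
}

# Compact synthetic-spectra spec for fast tests.
small_spec <- function(n_classes = 3, n_per_class = 10, seed = 7, ...) {
  synthetic_spec(n_classes = n_classes, n_per_class = n_per_class,
                 seed = seed, ...)
}

# Recovery-experiment spectra: a short 200-channel axis with five narrow
# single-channel bands whose heights vary monotonically across the three
# classes, plus band-free shared structure and noticeable noise, so that
# cross-validated PLS error genuinely improves as more informative channels
# are retained.
recovery_spec <- function(seed) {
  grid <- wavenumber_grid(400, 800, 2)
  centers <- c(450, 520, 600, 680, 760)
  heights <- rbind(c(0.0, 0.5, 0.0, 0.6, 0.1),
                   c(0.25, 0.25, 0.3, 0.3, 0.35),
                   c(0.5, 0.0, 0.6, 0.0, 0.6))
  class_peaks <- lapply(1:3, function(cl) {
    data.frame(center = centers, height = heights[cl, ], width = 0.7)
  })
  shared <- data.frame(center = c(480, 640, 720),
                       height = c(0.6, 0.8, 0.5), width = c(12, 14, 10))
  synthetic_spec(n_classes = 3, n_per_class = 70, grid = grid,
                 shared_peaks = shared, class_peaks = class_peaks,
                 baseline = 0.05, noise_sd = 0.1, gain_sd = 0.08,
                 band_height_sd = 0, seed = seed)
}
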