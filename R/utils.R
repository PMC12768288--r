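# Internal helpers shared across modules.

#' @importFrom stats predict rnorm runif sd var
#' @importFrom utils head read.csv write.csv
NULL

# Derive a per-stage child seed from a global seed and a stage tag, so one
# --seed fans out deterministically without correlated streams. Kept below
# 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 17
  for (ch in utf8ToInt(paste0(tag, ":", format(seed, scientific = FALSE)))) {
    h <- (h * 1000003 + ch) %% 2147483629  # stays exact in double precision
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; NULL seed
# means "use the current stream".
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Stratified fold assignment: returns an integer vector in 1..k, one entry
# per sample, with class proportions balanced across folds.
stratified_folds <- function(labels, k, seed = NULL) {
  labels <- as.factor(labels)
  if (k < 2) stop("k must be >= 2")
  if (min(table(labels)) < k) {
    stop("k (", k, ") exceeds the smallest class count (",
         min(table(labels)), ")")
  }
  with_seed_if(seed, {
    fold <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# One-hot encode a factor into an n x C numeric matrix (column per level).
one_hot <- function(f, levels = NULL) {
  f <- factor(f, levels = levels %||% levels(as.factor(f)))
  m <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cheap content fingerprint for stamping run artifacts (not cryptographic).
fingerprint <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

assert_finite_matrix <- function(X, what = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop(what, " must be numeric")
  bad <- which(apply(X, 2, function(col) any(!is.finite(col))))
  if (length(bad)) {
    stop(what, " contains non-finite values in column(s): ",
         paste(head(bad, 10), collapse = ", "))
  }
  X
}
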