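# Internal partial least squares regression (SIMPLS, de Jong 1993).
#
# CARS needs raw PLS regression coefficients inside a tight resampling loop,
# so a lean implementation is used; it is cross-checked against an
# independent PLS implementation in the test suite.

pls_fit <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  ncomp <- max(1L, min(ncomp, n - 1L, p))
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)

  R <- matrix(0, p, ncomp)  # X weights (applied to raw Xc)
  Q <- matrix(0, q, ncomp)  # Y loadings
  V <- matrix(0, p, ncomp)  # orthonormal basis of X loadings
  S <- crossprod(Xc, Yc)
  used <- 0L
  for (a in seq_len(ncomp)) {
    qa <- svd(S, nu = 0, nv = 1)$v[, 1]
    r <- S %*% qa
    t_scores <- Xc %*% r
    normt <- sqrt(sum(t_scores^2))
    if (normt < 1e-12) break
    t_scores <- t_scores / normt
    r <- r / normt
    pa <- crossprod(Xc, t_scores)
    Q[, a] <- crossprod(Yc, t_scores)
    R[, a] <- r
    va <- pa
    if (a > 1) {
      prev <- V[, seq_len(a - 1), drop = FALSE]
      va <- va - prev %*% crossprod(prev, pa)
    }
    nv <- sqrt(sum(va^2))
    if (nv < 1e-12) break
    va <- va / nv
    V[, a] <- va
    S <- S - va %*% crossprod(va, S)
    used <- a
  }
  if (used == 0L) {
    coef <- matrix(0, p, q)
  } else {
    idx <- seq_len(used)
    coef <- R[, idx, drop = FALSE] %*% t(Q[, idx, drop = FALSE])
  }
  list(coef = coef, intercept = ym - drop(crossprod(xm, coef)),
       ncomp = used, xmean = xm, ymean = ym)
}

pls_predict <- function(fit, X) {
  X <- as.matrix(X)
  sweep(X %*% fit$coef, 2, fit$intercept, `+`)
}

# Encode class labels as a numeric response for PLS regression.
encode_labels <- function(labels, encoding = c("integer", "one-hot")) {
  encoding <- match.arg(encoding)
  f <- as.factor(labels)
  if (encoding == "integer") {
    matrix(as.numeric(f), ncol = 1)
  } else {
    one_hot(f)
  }
}
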