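# Two-hidden-layer multilayer perceptron (ReLU, softmax output) trained by
# full-batch Adam. Kept deliberately small: the MLP classifier family in
# this package needs exactly the hidden_layer_sizes = (k1, k2) architecture,
# which no single-hidden-layer fitter provides.

mlp_fit <- function(X, y, k1, k2, epochs = 40, lr = 0.02, l2 = 1e-4,
                    seed = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  classes <- levels(y)
  n <- nrow(X); p <- ncol(X); C <- length(classes)
  mu <- colMeans(X)
  sg <- pmax(apply(X, 2, sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu), 2, sg, `/`)
  Yoh <- one_hot(y, classes)

  with_seed_if(seed, {
    W1 <- matrix(rnorm(p * k1, sd = sqrt(2 / p)), p, k1)
    W2 <- matrix(rnorm(k1 * k2, sd = sqrt(2 / k1)), k1, k2)
    W3 <- matrix(rnorm(k2 * C, sd = sqrt(2 / k2)), k2, C)
    b1 <- numeric(k1); b2 <- numeric(k2); b3 <- numeric(C)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
    m_t <- lapply(params, function(w) w * 0)
    v_t <- m_t
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    for (it in seq_len(epochs)) {
      Z1 <- sweep(Xs %*% params$W1, 2, params$b1, `+`); H1 <- pmax(Z1, 0)
      Z2 <- sweep(H1 %*% params$W2, 2, params$b2, `+`); H2 <- pmax(Z2, 0)
      Z3 <- sweep(H2 %*% params$W3, 2, params$b3, `+`)
      P <- exp(Z3 - apply(Z3, 1, max)); P <- P / rowSums(P)
      dZ3 <- (P - Yoh) / n
      g <- list(
        W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL,
        W3 = crossprod(H2, dZ3) + l2 * params$W3, b3 = colSums(dZ3))
      dH2 <- tcrossprod(dZ3, params$W3) * (Z2 > 0)
      g$W2 <- crossprod(H1, dH2) + l2 * params$W2
      g$b2 <- colSums(dH2)
      dH1 <- tcrossprod(dH2, params$W2) * (Z1 > 0)
      g$W1 <- crossprod(Xs, dH1) + l2 * params$W1
      g$b1 <- colSums(dH1)
      for (nm in names(params)) {
        m_t[[nm]] <- beta1 * m_t[[nm]] + (1 - beta1) * g[[nm]]
        v_t[[nm]] <- beta2 * v_t[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m_t[[nm]] / (1 - beta1^it)
        vhat <- v_t[[nm]] / (1 - beta2^it)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    list(params = params, mu = mu, sg = sg, classes = classes)
  })
}

mlp_prob <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, fit$mu), 2, fit$sg, `/`)
  p <- fit$params
  H1 <- pmax(sweep(Xs %*% p$W1, 2, p$b1, `+`), 0)
  H2 <- pmax(sweep(H1 %*% p$W2, 2, p$b2, `+`), 0)
  Z3 <- sweep(H2 %*% p$W3, 2, p$b3, `+`)
  P <- exp(Z3 - apply(Z3, 1, max))
  P <- P / rowSums(P)
  colnames(P) <- fit$classes
  P
}
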