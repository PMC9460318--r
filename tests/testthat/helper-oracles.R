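# Independent brute-force oracles used to cross-check the vectorized
# implementations. These stay deliberately naive (elementwise loops,
# literal matrix inversion) and share no code with the package internals.

# elementwise kernel evaluation, scalar math only
oracle_kernel_value <- function(spec, x, y) {
  p <- spec$params
  switch(spec$kind,
    polynomial = (sum(x * y) + p$a)^p$d,
    gaussian = exp(-sum((x - y)^2) / (2 * p$sigma^2)),
    wavelet = {
      u <- (x - y) / p$wa
      prod(cos(p$wb * u) * exp(-u^2 / p$wc))
    })
}

oracle_gram <- function(spec, X, Y = X) {
  K <- matrix(NA_real_, nrow(X), nrow(Y))
  for (i in seq_len(nrow(X)))
    for (j in seq_len(nrow(Y)))
      K[i, j] <- oracle_kernel_value(spec, X[i, ], Y[j, ])
  K
}

# squared MMD as the literal double sum over the three Gram blocks
oracle_mmd <- function(K, n_S, n_T) {
  is_ <- seq_len(n_S); it <- n_S + seq_len(n_T)
  ss <- 0; for (i in is_) for (j in is_) ss <- ss + K[i, j]
  tt <- 0; for (i in it) for (j in it) tt <- tt + K[i, j]
  st <- 0; for (i in is_) for (j in it) st <- st + K[i, j]
  ss / n_S^2 + tt / n_T^2 - 2 * st / (n_S * n_T)
}

# literal eigendecomposition of (mu I + K L K)^{-1} K H K
oracle_adaptation_eigen <- function(K, L, H, mu) {
  n <- nrow(K)
  A <- solve(mu * diag(n) + K %*% L %*% K) %*% (K %*% H %*% K)
  eigen(A)
}

# double-sum quadratic form alpha' K alpha
oracle_quadform <- function(alpha, K) {
  s <- 0
  for (i in seq_along(alpha))
    for (j in seq_along(alpha))
      s <- s + alpha[i] * alpha[j] * K[i, j]
  s
}

# squared MMD between two raw sample sets under a linear kernel,
# computed directly from the mean embeddings
oracle_linear_mmd <- function(A, B) {
  d <- colMeans(A) - colMeans(B)
  sum(d^2)
}

# gaussian-kernel MMD with the median-heuristic bandwidth, from samples
oracle_gaussian_mmd <- function(A, B) {
  X <- rbind(A, B)
  D <- as.matrix(stats::dist(X))
  sigma <- stats::median(D[upper.tri(D)])
  K <- exp(-D^2 / (2 * sigma^2))
  oracle_mmd(K, nrow(A), nrow(B))
}

random_kernel_spec <- function() {
  kind <- sample(c("polynomial", "gaussian", "wavelet"), 1L)
  switch(kind,
    polynomial = kernel_spec("polynomial", a = stats::runif(1, 0.1, 2),
                             d = sample(2:4, 1L)),
    gaussian = kernel_spec("gaussian", sigma = stats::runif(1, 0.5, 3)),
    wavelet = kernel_spec("wavelet", wa = stats::runif(1, 0.5, 2),
                          wb = stats::runif(1, 0.5, 2),
                          wc = stats::runif(1, 1, 3)))
}
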