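#' MMD coefficient matrix for stacked source/target samples
#'
#' The `(n_S + n_T)` square matrix `L` with entries `1/n_S^2` on the
#' source block, `1/n_T^2` on the target block and `-1/(n_S n_T)` on the
#' cross blocks, so that the squared MMD of a joint Gram `K` is
#' `sum(K * L)`. All entries of `L` sum to zero.
#'
#' @param n_S,n_T Source and target sample counts (>= 1).
#' @return The `(n_S + n_T) x (n_S + n_T)` matrix.
#' @export
build_L <- function(n_S, n_T) {
  if (n_S < 1L || n_T < 1L) stop("`n_S` and `n_T` must be at least 1")
  n <- n_S + n_T
  L <- matrix(-1 / (n_S * n_T), n, n)
  L[seq_len(n_S), seq_len(n_S)] <- 1 / n_S^2
  L[n_S + seq_len(n_T), n_S + seq_len(n_T)] <- 1 / n_T^2
  L
}

#' Centering matrix
#'
#' \eqn{H = I_n - (1/n) 1 1^\top}; idempotent and annihilates the
#' constant vector.
#'
#' @param n Dimension (>= 1).
#' @return The `n x n` centering matrix.
#' @export
build_H <- function(n) {
  if (n < 1L) stop("`n` must be at least 1")
  diag(n) - matrix(1 / n, n, n)
}

#' Squared maximum mean discrepancy from a joint Gram matrix
#'
#' Given the Gram matrix of the stacked source and target samples, returns
#' the squared MMD between the two empirical kernel mean embeddings,
#' computed in trace form as `sum(K * L)`. Small negative values from
#' floating-point cancellation (above -1e-10) are clamped to zero.
#'
#' @param K Joint Gram matrix, `(n_S + n_T)` square.
#' @param n_S,n_T Source and target sample counts.
#' @return Nonnegative squared MMD.
#' @export
mmd_distance <- function(K, n_S, n_T) {
  K <- as.matrix(K)
  n <- n_S + n_T
  if (nrow(K) != n || ncol(K) != n)
    stop(sprintf("`K` must be %d x %d for n_S = %d, n_T = %d",
                 n, n, n_S, n_T))
  v <- sum(K * build_L(n_S, n_T))
  max(v, 0)
}

#' Solve the MMD-minimizing subspace eigenproblem
#'
#' Finds the `m_dim` leading eigenvectors of
#' \eqn{(\mu I + K L K)^{-1} K H K} — the directions that retain the most
#' centered kernel variance per unit of (MMD + complexity) cost. The solve
#' goes through the symmetrized generalized eigenproblem
#' \eqn{K H K w = \lambda (\mu I + K L K) w} via a Cholesky factorization
#' of \eqn{\mu I + K L K} (positive definite for `mu > 0` and PSD `K L K`),
#' which is numerically stabler than the literal inversion but agrees with
#' it. Columns are normalized to unit Euclidean norm; eigenvalues are
#' attached as `attr(W, "eigenvalues")`.
#'
#' @param K Joint Gram matrix.
#' @param L MMD coefficient matrix from [build_L()].
#' @param H Centering matrix from [build_H()].
#' @param mu Positive trade-off regularizer.
#' @param m_dim Number of leading eigenvectors to keep.
#' @return Matrix `W` of `m_dim` unit-norm eigenvector columns.
#' @export
solve_adaptation <- function(K, L, H, mu, m_dim) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n || nrow(L) != n || nrow(H) != n)
    stop("`K`, `L`, `H` must be square matrices of matching size")
  if (mu <= 0) stop("`mu` must be positive")
  if (m_dim < 1L || m_dim > n)
    stop(sprintf("`m_dim` must be in 1..%d", n))

  KLK <- K %*% L %*% K
  KHK <- K %*% H %*% K
  B <- mu * diag(n) + (KLK + t(KLK)) / 2
  M <- (KHK + t(KHK)) / 2

  R <- tryCatch(chol(B), error = function(e)
    stop("mu*I + K L K is not positive definite; increase `mu` or check the kernel: ",
         conditionMessage(e)))
  # S = R^{-T} M R^{-1}, symmetric; eigenvectors map back via w = R^{-1} v
  Rinv <- backsolve(R, diag(n))
  S <- crossprod(Rinv, M %*% Rinv)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)

  rank_M <- sum(abs(es$values) > n * .Machine$double.eps * max(abs(es$values), 1))
  if (m_dim > rank_M)
    stop(sprintf("requested m_dim = %d exceeds the attainable rank %d of K H K",
                 m_dim, rank_M))

  W <- Rinv %*% es$vectors[, seq_len(m_dim), drop = FALSE]
  W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  attr(W, "eigenvalues") <- es$values[seq_len(m_dim)]
  W
}

#' Embed points through an adaptation subspace
#'
#' \eqn{Z = W^\top K}, where `K` has one row per joint training sample and
#' one column per point to embed; the result has `m_dim` rows and one
#' column per embedded point.
#'
#' @param W Eigenvector matrix from [solve_adaptation()].
#' @param K_new_vs_joint Kernel matrix, rows = joint training samples,
#'   columns = points to embed.
#' @return `m_dim x n_points` matrix of embedded coordinates.
#' @export
transform_features <- function(W, K_new_vs_joint) {
  K_new_vs_joint <- as.matrix(K_new_vs_joint)
  if (nrow(K_new_vs_joint) != nrow(W))
    stop("rows of the kernel matrix must match rows of `W` (joint sample count)")
  crossprod(W, K_new_vs_joint)
}

#' Marginal distribution adaptation of source and target features
#'
#' Builds the joint Gram of the stacked source and target features with a
#' (trained) multi-kernel, forms the MMD coefficient and centering matrices,
#' solves the regularized trace eigenproblem and returns the transformed
#' features in row-per-trial orientation together with the fitted
#' `adaptation_model` (which can embed points unseen at adaptation time via
#' their kernel columns against the joint training set).
#'
#' @param source,target [domain_dataset()] objects with equal feature
#'   dimension.
#' @param mk A [multi_kernel()] with trained weights.
#' @param mu Trade-off regularizer (default 1).
#' @param m_dim Subspace dimension (default: the feature dimension).
#' @return A list with `Z_S` (`n_S x m_dim`), `Z_T` (`n_T x m_dim`) and
#'   `model` (class `adaptation_model`).
#' @export
adapt_domains <- function(source, target, mk, mu = 1, m_dim = NULL) {
  stopifnot(inherits(source, "domain_dataset"),
            inherits(target, "domain_dataset"),
            inherits(mk, "multi_kernel"))
  if (ncol(source$X) != ncol(target$X))
    stop("source and target feature dimensions differ")
  if (is.null(m_dim)) m_dim <- ncol(source$X)
  n_S <- nrow(source$X); n_T <- nrow(target$X)
  X_joint <- rbind(source$X, target$X)
  K <- combined_gram(mk, X_joint, X_joint)
  L <- build_L(n_S, n_T)
  H <- build_H(n_S + n_T)
  W <- solve_adaptation(K, L, H, mu, m_dim)
  Z <- transform_features(W, K)   # m_dim x (n_S + n_T)
  model <- structure(
    list(W = W, mk = mk, X_joint = X_joint, n_S = n_S, n_T = n_T,
         mu = mu, m_dim = m_dim,
         orthogonality_residual = max(abs(crossprod(W, K %*% H %*% K %*% W) -
                                            diag(m_dim)))),
    class = "adaptation_model")
  list(Z_S = t(Z[, seq_len(n_S), drop = FALSE]),
       Z_T = t(Z[, n_S + seq_len(n_T), drop = FALSE]),
       model = model)
}

#' Embed new points with a fitted adaptation model
#'
#' @param object An `adaptation_model` from [adapt_domains()].
#' @param X_new Matrix of new points (rows) in the original feature space.
#' @param ... Unused.
#' @return `n_new x m_dim` matrix of adapted features.
#' @export
predict.adaptation_model <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(object$X_joint))
    stop("feature dimension of `X_new` does not match the adaptation features")
  K_new <- combined_gram(object$mk, object$X_joint, X_new)
  t(transform_features(object$W, K_new))
}

#' @export
print.adaptation_model <- function(x, ...) {
  cat(sprintf("<adaptation_model> n_S = %d, n_T = %d, m_dim = %d, mu = %g\n",
              x$n_S, x$n_T, x$m_dim, x$mu))
  invisible(x)
}
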