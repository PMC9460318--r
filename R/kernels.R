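#' Base kernel specification
#'
#' Three base kernel families are supported:
#' \describe{
#'   \item{polynomial}{\eqn{K(x, y) = (x \cdot y + a)^d} with offset `a` and
#'     integer degree `d`.}
#'   \item{gaussian}{\eqn{K(x, y) = \exp(-\|x - y\|^2 / (2\sigma^2))} with
#'     bandwidth `sigma`.}
#'   \item{wavelet}{translation-invariant wavelet kernel
#'     \eqn{K(x, y) = \prod_i h((x_i - y_i)/w_a)} with mother wavelet
#'     \eqn{h(u) = \cos(w_b u)\exp(-u^2 / w_c)}; `wa` is the dilation,
#'     `wb` the modulation frequency and `wc` the decay.}
#' }
#'
#' Defaults: `sigma = 1`, `a = 1`, `d = 2`, `wa = 1`, `wb = 1.75`, `wc = 2`
#' (the modulation 1.75 is the classical Morlet admissibility choice).
#' Note that wavelet kernels with aggressive `wb`/`wc` values, and polynomial
#' kernels with negative offsets, can fail positive semidefiniteness; use
#' [validate_gram()] to diagnose a fitted combination.
#'
#' @param kind `"polynomial"`, `"gaussian"` or `"wavelet"`.
#' @param a Polynomial offset.
#' @param d Polynomial degree, a positive integer (degrees 2-4 are the
#'   supported search grid).
#' @param sigma Gaussian bandwidth, positive.
#' @param wa,wb,wc Wavelet dilation (> 0), modulation frequency, decay (> 0).
#'
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("polynomial", "gaussian", "wavelet"),
                        a = 1, d = 2, sigma = 1,
                        wa = 1, wb = 1.75, wc = 2) {
  kind <- match.arg(kind)
  params <- switch(kind,
    polynomial = {
      if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
        stop("polynomial offset `a` must be a finite number")
      if (!is.numeric(d) || length(d) != 1L || d < 1 || d != round(d))
        stop("polynomial degree `d` must be a positive integer")
      list(a = a, d = as.integer(d))
    },
    gaussian = {
      if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
        stop("gaussian bandwidth `sigma` must be positive")
      list(sigma = sigma)
    },
    wavelet = {
      if (wa <= 0) stop("wavelet dilation `wa` must be positive")
      if (wc <= 0) stop("wavelet decay `wc` must be positive")
      list(wa = wa, wb = wb, wc = wc)
    })
  structure(list(kind = kind, params = params), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec %s> %s\n", x$kind,
              paste(names(x$params), unlist(x$params),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Weighted multi-kernel combination
#'
#' An ordered list of base kernels with nonnegative weights
#' \eqn{\gamma_p} constrained to the q-norm simplex
#' \eqn{\sum_p \gamma_p^q = 1}. The combined kernel is the linear mixture
#' \eqn{K(\cdot,\cdot;\gamma) = \sum_p \gamma_p k_p(\cdot,\cdot)}; a
#' nonnegative mixture of Mercer kernels is itself a Mercer kernel.
#'
#' @param kernels List of [kernel_spec()] objects.
#' @param gamma Nonnegative weight vector, same length as `kernels`. Defaults
#'   to the uniform point on the q-simplex, \eqn{\gamma_p = m^{-1/q}}.
#' @param q Norm exponent of the simplex constraint (default 2).
#'
#' @return An object of class `multi_kernel`.
#' @export
multi_kernel <- function(kernels, gamma = NULL, q = 2) {
  if (inherits(kernels, "kernel_spec")) kernels <- list(kernels)
  if (!length(kernels) || !all(vapply(kernels, inherits, TRUE, "kernel_spec")))
    stop("`kernels` must be a non-empty list of kernel_spec objects")
  m <- length(kernels)
  if (is.null(gamma)) gamma <- rep(m^(-1 / q), m)
  if (length(gamma) != m) stop("`gamma` length must match the kernel count")
  if (any(gamma < 0)) stop("kernel weights must be nonnegative")
  s <- sum(gamma^q)
  if (s <= 0) stop("kernel weights must not all be zero")
  if (abs(s - 1) > 1e-8)
    stop(sprintf("weights violate the q-simplex constraint: sum(gamma^q) = %g", s))
  structure(list(kernels = kernels, gamma = as.numeric(gamma), q = q),
            class = "multi_kernel")
}

#' @export
print.multi_kernel <- function(x, ...) {
  cat(sprintf("<multi_kernel> m = %d, q = %g\n", length(x$kernels), x$q))
  for (p in seq_along(x$kernels))
    cat(sprintf("  gamma[%d] = %.4f  %s(%s)\n", p, x$gamma[p],
                x$kernels[[p]]$kind,
                paste(names(x$kernels[[p]]$params),
                      unlist(x$kernels[[p]]$params),
                      sep = "=", collapse = ", ")))
  invisible(x)
}

#' Evaluate a base kernel on a pair of vectors
#'
#' @param spec A [kernel_spec()].
#' @param x,y Numeric vectors of equal length.
#' @return The scalar kernel value.
#' @export
eval_kernel <- function(spec, x, y) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(y))
    stop("`x` and `y` must have the same dimension")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("kernel inputs must be finite")
  gram_matrix(spec, matrix(x, nrow = 1L), matrix(y, nrow = 1L))[1L, 1L]
}

#' Gram matrix of a base kernel
#'
#' Entry `(i, j)` is the kernel applied to row `i` of `X` and row `j` of `Y`.
#' The computation is vectorized but contracts to match the elementwise
#' definition to 1e-12.
#'
#' @param spec A [kernel_spec()].
#' @param X,Y Numeric matrices (rows = points) with equal column counts.
#'   `Y` defaults to `X`.
#' @return The `nrow(X) x nrow(Y)` Gram matrix.
#' @export
gram_matrix <- function(spec, X, Y = X) {
  stopifnot(inherits(spec, "kernel_spec"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0L || nrow(Y) == 0L) stop("empty input to gram_matrix")
  if (ncol(X) != ncol(Y)) stop("feature dimensions of X and Y differ")
  p <- spec$params
  switch(spec$kind,
    polynomial = (tcrossprod(X, Y) + p$a)^p$d,
    gaussian = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * p$sigma^2))
    },
    wavelet = {
      K <- matrix(1, nrow(X), nrow(Y))
      for (j in seq_len(ncol(X))) {
        U <- outer(X[, j], Y[, j], "-") / p$wa
        K <- K * (cos(p$wb * U) * exp(-U^2 / p$wc))
      }
      K
    })
}

#' Gram matrix of a multi-kernel combination
#'
#' Computes \eqn{\sum_p \gamma_p K_p(X, Y)}.
#'
#' @param mk A [multi_kernel()].
#' @param X,Y Numeric matrices (rows = points).
#' @return The combined Gram matrix.
#' @export
combined_gram <- function(mk, X, Y = X) {
  stopifnot(inherits(mk, "multi_kernel"))
  K <- 0
  for (p in seq_along(mk$kernels))
    if (mk$gamma[p] != 0)
      K <- K + mk$gamma[p] * gram_matrix(mk$kernels[[p]], X, Y)
  K
}

#' Diagnose symmetry and positive semidefiniteness of a Gram matrix
#'
#' A valid (Mercer) kernel matrix must be symmetric and positive
#' semidefinite. This reports the maximum asymmetry and the minimum
#' eigenvalue of the symmetrized matrix, and flags a PSD violation when the
#' minimum eigenvalue falls below `-tol * max(|K|)`.
#'
#' @param K Square numeric matrix.
#' @param tol Relative tolerance for the PSD flag (default 1e-8).
#' @return A list with `max_asymmetry`, `min_eigenvalue`, `psd` (logical)
#'   and `symmetric` (logical).
#' @export
validate_gram <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("`K` must be square")
  asym <- max(abs(K - t(K)))
  Ks <- (K + t(K)) / 2
  ev <- eigen(Ks, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(K), 1e-300)
  list(max_asymmetry = asym,
       min_eigenvalue = min(ev),
       symmetric = asym <= tol * scale,
       psd = min(ev) >= -tol * scale)
}
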