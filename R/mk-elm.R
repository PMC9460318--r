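#' Closed-form kernel ELM training
#'
#' Solves the regularized dual system \eqn{(I/C + K)\alpha = T} by a single
#' symmetric linear solve (no explicit inverse). `K` is the training Gram
#' matrix and `T` the `+1/-1` targets; `C` trades off the output-weight norm
#' against the training error.
#'
#' @param K Square symmetric Gram matrix, `N x N`.
#' @param labels Numeric vector of `+1/-1` targets, length `N`.
#' @param C_reg Positive regularization constant.
#' @return The dual coefficient vector `alpha` (length `N`).
#' @export
train_kernel_elm <- function(K, labels, C_reg) {
  K <- as.matrix(K)
  N <- nrow(K)
  if (ncol(K) != N) stop("`K` must be square")
  if (length(labels) != N) stop("`labels` length must equal nrow(K)")
  if (!is.numeric(C_reg) || C_reg <= 0) stop("`C_reg` must be positive")
  A <- K + diag(N) / C_reg
  alpha <- tryCatch(
    solve(A, as.numeric(labels)),
    error = function(e) {
      # ridge jitter only on solve failure; the system is then re-attempted
      kap <- tryCatch(kappa(A, exact = FALSE), error = function(e2) NA_real_)
      warning(sprintf(
        "kernel ELM solve ill-conditioned (condition estimate %.3g); adding 1e-12 jitter",
        kap))
      tryCatch(solve(A + diag(N) * 1e-12, as.numeric(labels)),
               error = function(e2)
                 stop(sprintf(
                   "kernel ELM solve failed even with jitter (condition estimate %.3g)",
                   kap)))
    })
  as.numeric(alpha)
}

#' Per-kernel output-weight norms of the MK-ELM objective
#'
#' For each base kernel, the Frobenius norm of the scaled output weight
#' \eqn{\tilde\beta_p = \gamma_p \beta_p} reduces in the binary case to
#' \eqn{\|\tilde\beta_p\|_F = \gamma_p \sqrt{\alpha^\top K_p \alpha}}.
#' Slightly negative quadratic forms from non-PSD base kernels are clamped
#' to zero with a warning.
#'
#' @param gamma Current kernel weight vector.
#' @param alpha Dual coefficients from [train_kernel_elm()].
#' @param grams List of per-kernel Gram matrices on the training set.
#' @return Numeric vector of norms, one per base kernel.
#' @export
compute_betatilde_norms <- function(gamma, alpha, grams) {
  if (length(gamma) != length(grams))
    stop("`gamma` and `grams` must have the same length")
  vapply(seq_along(grams), function(p) {
    qf <- drop(crossprod(alpha, grams[[p]] %*% alpha))
    if (qf < -1e-10) {
      warning(sprintf(
        "negative quadratic form (%.3g) for base kernel %d; non-PSD kernel, clamped to 0",
        qf, p))
      qf <- 0
    }
    gamma[p] * sqrt(max(qf, 0))
  }, numeric(1))
}

#' Kernel-weight update on the q-norm simplex
#'
#' Closed-form minimizer of the multiple-kernel objective in the weights:
#' \eqn{\gamma_p = \|\tilde\beta_p\|_F^{2/(1+q)} /
#'   (\sum_p \|\tilde\beta_p\|_F^{2q/(1+q)})^{1/q}},
#' which lands exactly on the simplex \eqn{\sum_p \gamma_p^q = 1}.
#'
#' @param norms Nonnegative per-kernel norms, not all zero.
#' @param q Simplex exponent (default 2).
#' @return Updated weight vector on the q-simplex.
#' @export
update_gamma <- function(norms, q = 2) {
  if (any(norms < 0)) stop("`norms` must be nonnegative")
  if (all(norms == 0))
    stop("all per-kernel norms are zero: degenerate solution, cannot update weights")
  num <- norms^(2 / (1 + q))
  den <- sum(norms^(2 * q / (1 + q)))^(1 / q)
  g <- num / den
  # renormalize exactly onto the simplex against accumulated rounding
  g / sum(g^q)^(1 / q)
}

#' Train a multi-kernel extreme learning machine
#'
#' Alternating optimization of the kernel weights and the ELM dual solution:
#' starting from uniform weights on the q-simplex, each iteration
#' (i) forms the combined Gram with the current weights, (ii) solves the
#' regularized kernel-ELM system for `alpha`, (iii) evaluates the per-kernel
#' output-weight norms, and (iv) applies the closed-form weight update.
#' Iteration stops when `max |gamma_new - gamma_old| <= eps` or after
#' `max_iter` sweeps.
#'
#' @param source A labeled `source` [domain_dataset()].
#' @param kernels List of [kernel_spec()] base kernels (default: polynomial,
#'   Gaussian and wavelet at their default parameters).
#' @param C_reg Regularization constant (default 1).
#' @param q Simplex exponent (default 2).
#' @param eps Convergence tolerance on the weight change (default 1e-4).
#' @param max_iter Iteration cap (default 100).
#' @param gamma0 Optional initial weights; default uniform on the q-simplex.
#' @return A list with `model` (class `mkelm_model`: trained [multi_kernel()],
#'   `alpha`, `C_reg`, stored training features and labels) and `state`
#'   (class `mkelm_state`: weight history, iteration count, `converged`).
#' @export
train_mk_elm <- function(source, kernels = default_kernels(), C_reg = 1,
                         q = 2, eps = 1e-4, max_iter = 100L, gamma0 = NULL) {
  stopifnot(inherits(source, "domain_dataset"))
  if (is.null(source$labels)) stop("MK-ELM training requires a labeled source")
  if (length(unique(source$labels)) < 2L)
    stop("MK-ELM training requires both classes present")
  if (inherits(kernels, "kernel_spec")) kernels <- list(kernels)
  m <- length(kernels)
  X <- source$X
  T_vec <- as.numeric(source$labels)

  grams <- lapply(kernels, function(k) gram_matrix(k, X))
  gamma <- if (is.null(gamma0)) rep(m^(-1 / q), m) else {
    if (length(gamma0) != m) stop("`gamma0` length must match kernel count")
    gamma0 / sum(gamma0^q)^(1 / q)
  }

  history <- list(gamma)
  converged <- FALSE
  iter <- 0L
  alpha <- NULL
  repeat {
    iter <- iter + 1L
    Kc <- Reduce(`+`, Map(`*`, gamma, grams))
    alpha <- train_kernel_elm(Kc, T_vec, C_reg)
    if (m == 1L) { gamma <- 1; converged <- TRUE; history <- c(history, list(gamma)); break }
    norms <- compute_betatilde_norms(gamma, alpha, grams)
    gamma_new <- update_gamma(norms, q)
    history <- c(history, list(gamma_new))
    delta <- max(abs(gamma_new - gamma))
    gamma <- gamma_new
    if (delta <= eps) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning(sprintf("MK-ELM weight optimization did not converge in %d iterations", max_iter))

  # final solve at the converged weights
  Kc <- Reduce(`+`, Map(`*`, gamma, grams))
  alpha <- train_kernel_elm(Kc, T_vec, C_reg)

  mk <- multi_kernel(kernels, gamma = gamma, q = q)
  model <- structure(
    list(mk = mk, alpha = alpha, C_reg = C_reg, X_train = X, labels = source$labels),
    class = "mkelm_model")
  state <- structure(
    list(gamma_history = do.call(rbind, history), iterations = iter,
         converged = converged, eps = eps, max_iter = max_iter),
    class = "mkelm_state")
  list(model = model, state = state)
}

#' Default base kernel set
#'
#' The three-family mixture used throughout the pipeline: polynomial,
#' Gaussian and translation-invariant wavelet kernels at their default
#' parameters.
#'
#' @return A list of three [kernel_spec()] objects.
#' @export
default_kernels <- function() {
  list(kernel_spec("polynomial"), kernel_spec("gaussian"), kernel_spec("wavelet"))
}

#' Median-heuristic pairwise distance of a feature matrix
#'
#' The median Euclidean distance between rows, the standard bandwidth
#' heuristic for translation-invariant kernels. For large inputs a
#' deterministic subsample of rows (every k-th row, up to `max_rows`) is
#' used.
#'
#' @param X Numeric matrix (rows = trials).
#' @param max_rows Cap on the rows entering the distance computation.
#' @return The median pairwise distance (a positive scalar; falls back to 1
#'   if the median is zero).
#' @export
median_heuristic <- function(X, max_rows = 200L) {
  X <- as.matrix(X)
  if (nrow(X) > max_rows)
    X <- X[seq(1L, nrow(X), length.out = max_rows), , drop = FALSE]
  m <- stats::median(stats::dist(X))
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Data-scaled base kernel set
#'
#' The default three-family mixture with the length scales of the
#' translation-invariant members (Gaussian bandwidth, wavelet dilation) set
#' to the median pairwise distance of the supplied features. Kernel methods
#' are only informative when the bandwidth matches the data scale: far
#' below it every Gram matrix degenerates to the identity (pure
#' memorization), far above it to the constant matrix.
#'
#' @param X Feature matrix used to estimate the scale (for domain
#'   adaptation, the stacked source and target features).
#' @return A list of three [kernel_spec()] objects.
#' @export
scaled_kernels <- function(X) {
  s <- median_heuristic(X)
  list(kernel_spec("polynomial"),
       kernel_spec("gaussian", sigma = s),
       kernel_spec("wavelet", wa = s))
}

#' Predict with a trained (multi-)kernel ELM
#'
#' Decision scores are `combined_gram(mk, X_new, X_train) %*% alpha`; labels
#' are their signs, with `sign(0)` mapped to `+1` by convention.
#'
#' @param model A trained `mkelm_model`.
#' @param X_new Matrix of new points (rows) with the training feature
#'   dimension.
#' @return A list with `scores` and `labels`.
#' @export
predict_kernel_elm <- function(model, X_new) {
  stopifnot(inherits(model, "mkelm_model"))
  X_new <- as.matrix(X_new)
  if (nrow(X_new) == 0L)
    return(list(scores = numeric(0), labels = integer(0)))
  if (ncol(X_new) != ncol(model$X_train))
    stop("feature dimension of `X_new` does not match the training features")
  scores <- drop(combined_gram(model$mk, X_new, model$X_train) %*% model$alpha)
  labels <- ifelse(scores >= 0, 1L, -1L)
  list(scores = as.numeric(scores), labels = as.integer(labels))
}

#' @export
print.mkelm_model <- function(x, ...) {
  cat(sprintf("<mkelm_model> N = %d training trials, C = %g\n",
              nrow(x$X_train), x$C_reg))
  print(x$mk)
  invisible(x)
}
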