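# Minimal from-scratch CART classifier (gini impurity, axis-aligned splits,
# grown to purity) used as an independent reference for the random-forest
# contract tests.

ref_tree_fit <- function(X, y, min_leaf = 1L) {
  grow <- function(idx) {
    ys <- y[idx]
    if (length(unique(ys)) == 1L || length(idx) <= min_leaf)
      return(list(leaf = TRUE,
                  label = if (sum(ys == 1L) >= sum(ys == -1L)) 1L else -1L))
    best <- NULL
    for (j in seq_len(ncol(X))) {
      v <- sort(unique(X[idx, j]))
      if (length(v) < 2L) next
      cuts <- (v[-1] + v[-length(v)]) / 2
      for (cut in cuts) {
        l <- idx[X[idx, j] <= cut]; r <- idx[X[idx, j] > cut]
        gini <- function(s) {
          p <- mean(y[s] == 1L); 2 * p * (1 - p)
        }
        score <- length(l) * gini(l) + length(r) * gini(r)
        if (is.null(best) || score < best$score)
          best <- list(score = score, j = j, cut = cut, l = l, r = r)
      }
    }
    if (is.null(best))
      return(list(leaf = TRUE,
                  label = if (sum(ys == 1L) >= sum(ys == -1L)) 1L else -1L))
    list(leaf = FALSE, j = best$j, cut = best$cut,
         left = grow(best$l), right = grow(best$r))
  }
  grow(seq_len(nrow(X)))
}

ref_tree_predict <- function(tree, X) {
  one <- function(node, x) {
    if (node$leaf) return(node$label)
    if (x[node$j] <= node$cut) one(node$left, x) else one(node$right, x)
  }
  vapply(seq_len(nrow(X)), function(i) one(tree, X[i, ]), integer(1))
}

# two Gaussian classes separated along the first feature axis
make_gaussian_classes <- function(n_per_class, dim = 4L, sep = 3, seed = 1L) {
  set.seed(seed)
  lab <- rep(c(1L, -1L), n_per_class)
  X <- matrix(stats::rnorm(2L * n_per_class * dim), ncol = dim)
  X[, 1L] <- X[, 1L] + lab * sep / 2
  domain_dataset(X, lab, "source")
}
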