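#' Random forest configuration
#'
#' Bagged unpruned classification trees with feature subsampling. The
#' subset size follows the `log2(M)` rule: with `M` features, each tree
#' (or node, see `per_node`) considers `floor(log2(M))` features — 3 for
#' the default 10-dimensional CSP feature vector.
#'
#' @param k_trees Number of trees (the model-selection grid is
#'   `{10, 20, 50}`; default 50).
#' @param feature_subset Features drawn per tree without replacement;
#'   default `floor(log2(M))`, resolved at training time.
#' @param min_leaf Minimum observations per leaf (default 1: unpruned,
#'   fully grown trees).
#' @param per_node If `TRUE`, resample the feature subset at every node
#'   (the classical variant) instead of once per tree.
#' @param seed RNG seed for bootstrap and feature draws.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(k_trees = 50L, feature_subset = NULL, min_leaf = 1L,
                      per_node = FALSE, seed = 1L) {
  if (k_trees < 1L) stop("`k_trees` must be >= 1")
  if (!is.null(feature_subset) && feature_subset < 1L)
    stop("`feature_subset` must be >= 1")
  structure(list(k_trees = as.integer(k_trees),
                 feature_subset = if (is.null(feature_subset)) NULL
                                  else as.integer(feature_subset),
                 min_leaf = as.integer(min_leaf),
                 per_node = isTRUE(per_node), seed = as.integer(seed)),
            class = "rf_config")
}

.resolve_subset <- function(cfg, M) {
  m <- if (is.null(cfg$feature_subset)) max(1L, floor(log2(M))) else cfg$feature_subset
  if (m > M) stop(sprintf("feature_subset = %d exceeds the %d available features", m, M))
  m
}

#' Train a random forest
#'
#' Per tree: a bootstrap resample of the training trials, a feature subset
#' of size `feature_subset` drawn without replacement, and a fully grown
#' (unpruned) classification tree on that subset. With `per_node = TRUE`
#' the per-node feature resampling variant is used instead. Training is
#' deterministic given `cfg$seed`.
#'
#' @param data A labeled [domain_dataset()] with both classes present.
#' @param cfg An [rf_config()].
#' @return An object of class `rf_model`.
#' @export
train_rf <- function(data, cfg = rf_config()) {
  stopifnot(inherits(data, "domain_dataset"), inherits(cfg, "rf_config"))
  if (is.null(data$labels)) stop("random forest training requires labels")
  if (length(unique(data$labels)) < 2L)
    stop("random forest training requires both classes present")
  X <- data$X
  M <- ncol(X)
  n <- nrow(X)
  m <- .resolve_subset(cfg, M)
  colnames(X) <- paste0("f", seq_len(M))

  fitted <- .with_local_seed(cfg$seed, {
    if (cfg$per_node) {
      rf <- randomForest::randomForest(
        x = X, y = factor(data$labels, levels = c(-1L, 1L)),
        ntree = cfg$k_trees, mtry = m, nodesize = cfg$min_leaf,
        replace = TRUE)
      list(backend = "per_node", forest = rf)
    } else {
      trees <- vector("list", cfg$k_trees)
      for (k in seq_len(cfg$k_trees)) {
        boot <- sample.int(n, n, replace = TRUE)
        feats <- sort(sample.int(M, m, replace = FALSE))
        df <- data.frame(X[boot, feats, drop = FALSE])
        df$.y <- factor(data$labels[boot], levels = c(-1L, 1L))
        fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                            control = rpart::rpart.control(
                              cp = 0, minsplit = 2L,
                              minbucket = cfg$min_leaf,
                              maxdepth = 30L, xval = 0L,
                              maxcompete = 0L, maxsurrogate = 0L))
        trees[[k]] <- list(fit = fit, feats = feats)
      }
      list(backend = "per_tree", trees = trees)
    }
  })
  structure(c(fitted, list(config = cfg, classes = c(-1L, 1L), M = M)),
            class = "rf_model")
}

#' Predict with a random forest
#'
#' Per-sample majority vote over tree predictions; ties are broken toward
#' `+1` (fixed convention).
#'
#' @param model An `rf_model`.
#' @param X Feature matrix with the training dimension.
#' @return Integer vector of `+1/-1` predictions.
#' @export
predict_rf <- function(model, X) {
  stopifnot(inherits(model, "rf_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$M)
    stop(sprintf("feature dimension %d does not match the %d training features",
                 ncol(X), model$M))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  votes <- rf_votes(model, X)
  ifelse(votes[, "1"] >= votes[, "-1"], 1L, -1L)
}

#' Per-class vote counts of a random forest
#'
#' @param model An `rf_model`.
#' @param X Feature matrix.
#' @return Matrix with columns `"-1"` and `"1"` of per-sample vote counts
#'   (summing to `k_trees`).
#' @export
rf_votes <- function(model, X) {
  stopifnot(inherits(model, "rf_model"))
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  if (model$backend == "per_node") {
    pr <- stats::predict(model$forest, newdata = data.frame(X), type = "vote",
                         norm.votes = FALSE)
    out <- matrix(0, n, 2L, dimnames = list(NULL, c("-1", "1")))
    out[, colnames(pr)] <- pr
    return(out)
  }
  counts <- matrix(0L, n, 2L, dimnames = list(NULL, c("-1", "1")))
  df_all <- data.frame(X)
  for (tr in model$trees) {
    p <- stats::predict(tr$fit, newdata = df_all, type = "class")
    p <- as.character(p)
    counts[, "1"] <- counts[, "1"] + (p == "1")
    counts[, "-1"] <- counts[, "-1"] + (p == "-1")
  }
  counts
}

#' @export
print.rf_model <- function(x, ...) {
  k <- if (x$backend == "per_node") x$forest$ntree else length(x$trees)
  cat(sprintf("<rf_model> %d trees (%s feature subsampling), %d features\n",
              k, if (x$backend == "per_node") "per-node" else "per-tree", x$M))
  invisible(x)
}
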