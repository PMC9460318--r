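#' Classification performance metrics
#'
#' Accuracy (percent), Cohen's kappa, recall, precision and F1 for the `+1`
#' class, the confusion matrix, and — when decision scores are supplied —
#' the AUC computed as the rank (Mann-Whitney) statistic.
#'
#' @param pred Predicted `+1/-1` labels.
#' @param truth True `+1/-1` labels, same length.
#' @param scores Optional real-valued decision scores (larger = more `+1`).
#' @return An object of class `bci_metrics`: a list with `accuracy` (in
#'   percent), `kappa`, `recall`, `precision`, `f1`, `auc` (or `NA`),
#'   and `confusion` (`TP`, `FN`, `FP`, `TN`).
#' @export
evaluate_predictions <- function(pred, truth, scores = NULL) {
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have the same length")
  pred <- as.integer(pred); truth <- as.integer(truth)
  n <- length(truth)
  TP <- sum(pred == 1L & truth == 1L)
  FN <- sum(pred == -1L & truth == 1L)
  FP <- sum(pred == 1L & truth == -1L)
  TN <- sum(pred == -1L & truth == -1L)
  acc <- (TP + TN) / n
  # chance-corrected agreement
  pe <- ((TP + FP) * (TP + FN) + (TN + FN) * (TN + FP)) / n^2
  kappa <- if (pe >= 1) 0 else (acc - pe) / (1 - pe)
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  f1 <- if (is.finite(precision) && is.finite(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(scores) != n) stop("`scores` length must match `truth`")
    if (length(unique(truth)) == 2L) {
      r <- suppressMessages(pROC::roc(response = truth, predictor = scores,
                                      levels = c(-1, 1), direction = "<",
                                      quiet = TRUE))
      auc <- as.numeric(r$auc)
    }
  }
  structure(list(accuracy = 100 * acc, kappa = kappa, recall = recall,
                 precision = precision, f1 = f1, auc = auc,
                 confusion = c(TP = TP, FN = FN, FP = FP, TN = TN)),
            class = "bci_metrics")
}

#' @export
print.bci_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  kappa %.3f  precision %.3f  recall %.3f  F1 %.3f",
              x$accuracy, x$kappa, x$precision, x$recall, x$f1))
  if (is.finite(x$auc)) cat(sprintf("  AUC %.3f", x$auc))
  cat("\n  confusion: ", paste(names(x$confusion), x$confusion,
                               sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the settings of every stage. The hyperparameter grids mirror
#' the standard search space: regularization
#' `C in {0.001, 0.01, 0.1, 1, 10, 50, 100}`, Gaussian bandwidth and
#' polynomial offset over the same seven values, polynomial degree in
#' `{2, 3, 4}`, wavelet parameters over the same seven values, and forest
#' size `k in {10, 20, 50}`. By default the pipeline runs at fixed default
#' hyperparameters; `tune = TRUE` selects `C` and `sigma` on a reduced
#' lattice by stratified 5-fold cross-validation on the source only (no
#' target labels are ever touched during model selection).
#'
#' @param kernels Base kernel list. The default `NULL` resolves at run time
#'   to [scaled_kernels()] on the stacked source and target features, so the
#'   Gaussian bandwidth and wavelet dilation match the data scale.
#' @param C_reg ELM regularization (default 1).
#' @param q,eps,max_iter MK-ELM weight-optimization settings.
#' @param mu Adaptation trade-off regularizer (default 1).
#' @param m_dim Adaptation subspace dimension (default: feature dimension).
#' @param k_trees Forest size (default 50).
#' @param rf_seed Forest RNG seed.
#' @param adaptation `"mkmmd"` for the full method, `"none"` for the
#'   no-adaptation baseline (the raw-feature forest).
#' @param tune Grid-search `C` and `sigma` by source-only CV.
#' @param C_grid,sigma_grid,a_grid,d_grid,w_grid,k_grid Search grids.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(kernels = NULL, C_reg = 1,
                            q = 2, eps = 1e-4, max_iter = 100L,
                            mu = 1, m_dim = NULL,
                            k_trees = 50L, rf_seed = 1L,
                            adaptation = c("mkmmd", "none"),
                            tune = FALSE,
                            C_grid = c(0.001, 0.01, 0.1, 1, 10, 50, 100),
                            sigma_grid = c(0.001, 0.01, 0.1, 1, 10, 50, 100),
                            a_grid = c(0.001, 0.01, 0.1, 1, 10, 50, 100),
                            d_grid = c(2, 3, 4),
                            w_grid = c(0.001, 0.01, 0.1, 1, 10, 50, 100),
                            k_grid = c(10, 20, 50)) {
  adaptation <- match.arg(adaptation)
  for (g in list(C_grid, sigma_grid, a_grid, d_grid, w_grid, k_grid))
    if (!length(g)) stop("hyperparameter grids must be nonempty")
  structure(list(kernels = kernels, C_reg = C_reg, q = q, eps = eps,
                 max_iter = as.integer(max_iter), mu = mu, m_dim = m_dim,
                 k_trees = as.integer(k_trees), rf_seed = as.integer(rf_seed),
                 adaptation = adaptation, tune = isTRUE(tune),
                 C_grid = C_grid, sigma_grid = sigma_grid, a_grid = a_grid,
                 d_grid = d_grid, w_grid = w_grid, k_grid = k_grid),
            class = "pipeline_config")
}

# stratified k-fold CV accuracy of MK-ELM on the source, used for
# source-only model selection
.source_cv_accuracy <- function(source, kernels, C_reg, q, folds = 5L,
                                seed = 1L) {
  n <- nrow(source$X)
  fold_id <- .with_local_seed(seed, {
    id <- integer(n)
    for (cl in c(-1L, 1L)) {
      idx <- which(source$labels == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    if (length(unique(source$labels[tr])) < 2L) next
    fit <- suppressWarnings(train_mk_elm(
      domain_dataset(source$X[tr, , drop = FALSE], source$labels[tr], "source"),
      kernels = kernels, C_reg = C_reg, q = q))
    pr <- predict_kernel_elm(fit$model, source$X[te, , drop = FALSE])
    correct <- correct + sum(pr$labels == source$labels[te])
  }
  correct / n
}

.tune_hyperparameters <- function(source, cfg) {
  best <- list(acc = -Inf, C = cfg$C_reg, sigma = NULL)
  for (C in cfg$C_grid) for (sg in cfg$sigma_grid) {
    kernels <- lapply(cfg$kernels, function(k) {
      if (k$kind == "gaussian") kernel_spec("gaussian", sigma = sg) else k
    })
    acc <- .source_cv_accuracy(source, kernels, C, cfg$q)
    if (acc > best$acc) best <- list(acc = acc, C = C, sigma = sg)
  }
  kernels <- lapply(cfg$kernels, function(k) {
    if (k$kind == "gaussian" && !is.null(best$sigma))
      kernel_spec("gaussian", sigma = best$sigma) else k
  })
  list(kernels = kernels, C_reg = best$C, cv_accuracy = best$acc)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full multi-kernel domain-adaptation + random-forest pipeline
#'
#' Source features train the multi-kernel ELM (learning the kernel weights
#' that maximize class separability); the learned combined kernel then
#' drives the MK-MMD marginal-distribution alignment of source and target;
#' finally a random forest is trained on the adapted source features and
#' applied to the adapted target features. With `adaptation = "none"` the
#' forest runs on the raw features instead (baseline).
#'
#' @param source Labeled source [domain_dataset()].
#' @param target Target [domain_dataset()]; labels, when present, are used
#'   only to compute metrics.
#' @param cfg A [pipeline_config()].
#' @return A list with `predictions`, `metrics` (when target labels were
#'   available, else `NULL`) and `bundle` (trained models, configuration
#'   and kernel weights).
#' @export
run_mk_da_rf <- function(source, target, cfg = pipeline_config()) {
  stopifnot(inherits(source, "domain_dataset"),
            inherits(target, "domain_dataset"),
            inherits(cfg, "pipeline_config"))
  kernels <- cfg$kernels; C_reg <- cfg$C_reg; cv_acc <- NA_real_
  if (is.null(kernels))
    kernels <- scaled_kernels(rbind(source$X, target$X))
  if (cfg$tune) {
    cfg$kernels <- kernels
    tuned <- .stage("tune", .tune_hyperparameters(source, cfg))
    kernels <- tuned$kernels; C_reg <- tuned$C_reg; cv_acc <- tuned$cv_accuracy
  }
  elm <- .stage("mk_elm", train_mk_elm(source, kernels = kernels,
                                       C_reg = C_reg, q = cfg$q,
                                       eps = cfg$eps, max_iter = cfg$max_iter))
  if (cfg$adaptation == "mkmmd") {
    ad <- .stage("adapt", adapt_domains(source, target, elm$model$mk,
                                        mu = cfg$mu, m_dim = cfg$m_dim))
    Z_S <- ad$Z_S; Z_T <- ad$Z_T; ad_model <- ad$model
  } else {
    Z_S <- source$X; Z_T <- target$X; ad_model <- NULL
  }
  rf <- .stage("random_forest",
               train_rf(domain_dataset(Z_S, source$labels, "source"),
                        rf_config(k_trees = cfg$k_trees, seed = cfg$rf_seed)))
  pred <- .stage("predict", predict_rf(rf, Z_T))
  votes <- rf_votes(rf, Z_T)
  scores <- (votes[, "1"] - votes[, "-1"]) / cfg$k_trees
  metrics <- if (!is.null(target$labels))
    evaluate_predictions(pred, target$labels, scores) else NULL
  bundle <- list(mkelm = elm$model, mkelm_state = elm$state,
                 adaptation = ad_model, forest = rf, config = cfg,
                 gamma = elm$model$mk$gamma, source_cv_accuracy = cv_acc)
  list(predictions = pred, metrics = metrics, bundle = bundle)
}

#' Save / load a trained pipeline bundle
#'
#' Serializes the model bundle (kernel weights, ELM dual coefficients,
#' adaptation subspace, forest and configuration) to a single archive;
#' reloading reproduces predictions exactly.
#'
#' @param bundle The `bundle` element of a [run_mk_da_rf()] result.
#' @param path File path.
#' @return `load_bundle` returns the restored bundle.
#' @export
save_bundle <- function(bundle, path) {
  saveRDS(bundle, path, version = 3L)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readRDS(path)
}
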