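test_that("generators are deterministic and leave global RNG state alone", {
  cfg <- sim_config(n_trials = 5, n_channels = 6, seed = 42)
  e1 <- gen_mi_eeg_epochs(cfg)
  e2 <- gen_mi_eeg_epochs(cfg)
  expect_identical(e1$data, e2$data)

  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(gen_mi_eeg_epochs(cfg)); after <- rnorm(3)
  expect_identical(before, after)

  d1 <- gen_feature_domains(seed = 7)
  d2 <- gen_feature_domains(seed = 7)
  expect_identical(d1$source$X, d2$source$X)
  expect_identical(d1$target$X, d2$target$X)
})

test_that("generators honor the requested per-class counts", {
  e <- gen_mi_eeg_epochs(sim_config(n_trials = 13, n_channels = 4, seed = 2))
  expect_equal(sum(e$labels == 1L), 13)
  expect_equal(sum(e$labels == -1L), 13)
  expect_true(all(is.finite(e$data)))
  expect_equal(dim(e$data)[3], round(4 * 100))

  d <- gen_feature_domains(n_s = 9, n_t = 7, dim = 5, seed = 3)
  expect_equal(sum(d$source$labels == 1L), 9)
  expect_equal(sum(d$target_labels == -1L), 7)
})

test_that("configuration errors name the offending field", {
  expect_error(sim_config(erd_depth = 1.5), "erd_depth")
  expect_error(sim_config(n_channels = 4, erd_channels = c(1, 9)),
               "erd_channels")
  expect_error(shift_config(gain_drift = c(1, -1)), "gain_drift")
  expect_error(gen_feature_domains(class_sep = -1), "class_sep")
  expect_error(gen_feature_domains(dim = 1), "dim")
})

test_that("identity shift is a no-op and labels always survive the shift", {
  e <- gen_mi_eeg_epochs(sim_config(n_trials = 6, n_channels = 6, seed = 4))
  id <- apply_domain_shift(e, shift_config())
  expect_equal(id$data, e$data)
  expect_identical(id$labels, e$labels)

  sh <- apply_domain_shift(e, shift_config(gain_drift = 1.3,
                                           extra_noise_sd = 1,
                                           mixing_rotation_angle = 0.4,
                                           seed = 9))
  expect_identical(sh$labels, e$labels)
  expect_gt(max(abs(sh$data - e$data)), 0.1)
  expect_error(apply_domain_shift(e, shift_config(gain_drift = rep(1, 3))),
               "channels")
})

test_that("channel rotation mixes orthogonally", {
  R <- mkdarf:::.adjacent_rotation(6, 0.3)
  expect_equal(crossprod(R), diag(6), tolerance = 1e-12)
})

test_that("zero ERD depth removes the class signal from CSP features", {
  # fit CSP on an independent draw so in-sample overfitting does not
  # fabricate spurious class separation in the evaluation features
  e_fit <- gen_mi_eeg_epochs(sim_config(n_trials = 100, n_channels = 8,
                                        erd_depth = 0, seed = 111))
  e <- gen_mi_eeg_epochs(sim_config(n_trials = 100, n_channels = 8,
                                    erd_depth = 0, seed = 11))
  m <- fit_csp(preprocess_epochs(e_fit, target_fs = NULL), n_pairs = 2)
  p <- preprocess_epochs(e, target_fs = NULL)
  f <- csp_features(m, p)
  smd <- vapply(seq_len(ncol(f$X)), function(j) {
    a <- f$X[f$labels == 1L, j]; b <- f$X[f$labels == -1L, j]
    abs(mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
  }, numeric(1))
  expect_lt(max(smd), 0.3)
})

test_that("a real domain shift increases the feature-space MMD", {
  worse <- 0L
  for (s in 1:20) {
    e <- gen_mi_eeg_epochs(sim_config(n_trials = 25, n_channels = 8,
                                      seed = 300 + s))
    e_twin <- gen_mi_eeg_epochs(sim_config(n_trials = 25, n_channels = 8,
                                           seed = 600 + s))
    e_shift <- apply_domain_shift(e_twin,
      shift_config(mixing_rotation_angle = 0.3, extra_noise_sd = 2,
                   seed = s))
    feats <- function(x) {
      p <- preprocess_epochs(x, target_fs = NULL)
      csp_features(fit_csp(p, n_pairs = 2), p)$X
    }
    base <- feats(e)
    mmd_shift <- oracle_gaussian_mmd(base, feats(e_shift))
    mmd_null <- oracle_gaussian_mmd(base, feats(e_twin))
    if (mmd_shift > mmd_null) worse <- worse + 1L
  }
  expect_gte(worse, 18L)
})

test_that("decoding accuracy grows with ERD depth", {
  cv_acc <- function(depth, seed) {
    e <- gen_mi_eeg_epochs(sim_config(n_trials = 30, n_channels = 8,
                                      erd_depth = depth, seed = seed))
    p <- preprocess_epochs(e, target_fs = NULL)
    folds <- rep_len(1:5, n_trials(p))
    correct <- 0L
    for (f in 1:5) {
      tr <- which(folds != f); te <- which(folds == f)
      etr <- eeg_epochs(p$data[tr, , , drop = FALSE], p$fs, p$labels[tr],
                        p$channel_names, p$t0)
      ete <- eeg_epochs(p$data[te, , , drop = FALSE], p$fs, NULL,
                        p$channel_names, p$t0)
      m <- fit_csp(etr, n_pairs = 2)
      rf <- train_rf(csp_features(m, etr), rf_config(k_trees = 20, seed = 1))
      pred <- predict_rf(rf, csp_features(m, ete)$X)
      correct <- correct + sum(pred == p$labels[te])
    }
    correct / n_trials(p)
  }
  viol <- 0L
  for (s in 1:10) {
    accs <- vapply(c(0, 0.3, 0.7), cv_acc, numeric(1), seed = 400 + s)
    viol <- viol + sum(diff(accs) < -0.05)
  }
  expect_lte(viol, 1L)
})

test_that("feature domains follow the requested geometry", {
  # identity shift: empirical domain means agree up to sampling error
  d <- gen_feature_domains(n_s = 400, n_t = 400, dim = 4, class_sep = 0,
                           seed = 19)
  expect_lt(sqrt(sum((colMeans(d$source$X) - colMeans(d$target$X))^2)), 0.25)

  # class_sep = 0 leaves any classifier at chance on the target
  accs <- vapply(1:20, function(s) {
    d0 <- gen_feature_domains(n_s = 100, n_t = 100, dim = 4, class_sep = 0,
                              seed = 500 + s)
    rf <- train_rf(d0$source, rf_config(k_trees = 20, seed = 1))
    mean(predict_rf(rf, d0$target$X) == d0$target_labels)
  }, numeric(1))
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)
})

test_that("a mean shift degrades transfer below within-source accuracy", {
  deltas <- vapply(1:20, function(s) {
    d <- gen_feature_domains(n_s = 50, n_t = 50, dim = 6, class_sep = 3,
                             shift = shift_config(mean_offset = 2, seed = s),
                             seed = 700 + s)
    rf <- train_rf(d$source, rf_config(k_trees = 20, seed = 1))
    tgt_acc <- mean(predict_rf(rf, d$target$X) == d$target_labels)
    folds <- rep_len(1:5, nrow(d$source$X))
    cv_correct <- 0L
    for (f in 1:5) {
      tr <- which(folds != f); te <- which(folds == f)
      rf_f <- train_rf(domain_dataset(d$source$X[tr, ], d$source$labels[tr],
                                      "source"),
                       rf_config(k_trees = 20, seed = 1))
      cv_correct <- cv_correct + sum(predict_rf(rf_f, d$source$X[te, ]) ==
                                       d$source$labels[te])
    }
    tgt_acc - cv_correct / nrow(d$source$X)
  }, numeric(1))
  expect_lt(mean(deltas), 0)
})

test_that("epochs and feature files round-trip", {
  e <- gen_mi_eeg_epochs(sim_config(n_trials = 4, n_channels = 5, seed = 21))
  tf <- tempfile(fileext = ".rds")
  save_epochs(e, tf)
  e2 <- load_epochs(tf)
  expect_identical(e2$data, e$data)
  expect_identical(e2$labels, e$labels)
  expect_identical(e2$channel_names, e$channel_names)

  bad <- tempfile()
  writeLines("not an epochs file", bad)
  expect_error(load_epochs(bad), "parse|format")
  expect_error(load_epochs(tempfile()), "not found")

  d <- gen_feature_domains(n_s = 5, n_t = 5, dim = 3, seed = 22)
  fc <- tempfile(fileext = ".csv")
  write_feature_csv(d$source, fc)
  hdr <- readLines(fc, n = 1)
  expect_match(hdr, "f1.*f2.*f3.*label")
  back <- read_feature_csv(fc, role = "source")
  expect_equal(back$X, d$source$X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$labels, d$source$labels)
})
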