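# single-trial epochs holder around a channels x samples matrix
as_epochs <- function(M, fs, labels = NULL, names = NULL) {
  eeg_epochs(array(M, dim = c(1, nrow(M), ncol(M))), fs, labels,
             names %||% paste0("ch", seq_len(nrow(M))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fft_amplitude <- function(x, fs, f) {
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  sp[round(f * n / fs) + 1]
}

test_that("channel selection reorders, subsets, and reports missing names", {
  e <- gen_mi_eeg_epochs(sim_config(n_trials = 3, n_channels = 20, seed = 1))
  expect_equal(select_channels(e, e$channel_names)$data, e$data)

  # a 62-channel montage containing the motor strip among other sites
  extra <- paste0("X", 1:42)
  full_names <- c(extra[1:21], motor_channels_20(), extra[22:42])
  e62 <- eeg_epochs(array(rnorm(2 * 62 * 50), c(2, 62, 50)), 100,
                    channel_names = full_names)
  sub <- select_channels(e62)
  expect_equal(sub$channel_names, motor_channels_20())
  expect_equal(dim(sub$data)[2], 20)
  expect_equal(sub$data[1, 1, ], e62$data[1, 22, ])
  expect_error(select_channels(e62, c("C3", "Nope")), "Nope")
})

test_that("band-pass keeps the passband, rejects stopbands and kills DC", {
  fs <- 100; t <- (0:599) / fs
  mk_tone <- function(f) as_epochs(matrix(sin(2 * pi * f * t), 1), fs)

  in_band <- bandpass_filter(mk_tone(20))
  expect_equal(fft_amplitude(in_band$data[1, 1, ], fs, 20), 1,
               tolerance = 0.05)

  low <- bandpass_filter(mk_tone(2))
  atten_db <- 20 * log10(fft_amplitude(low$data[1, 1, ], fs, 2) / 1)
  expect_lt(atten_db, -20)

  high <- bandpass_filter(mk_tone(45))
  expect_lt(20 * log10(fft_amplitude(high$data[1, 1, ], fs, 45)), -20)

  dc <- bandpass_filter(as_epochs(matrix(1, 1, 600), fs))
  expect_lt(abs(mean(dc$data)), 1e-6)

  expect_error(bandpass_filter(mk_tone(20), low_hz = 8, high_hz = 60),
               "fs/2")
})

test_that("downsampling reduces the sample count and preserves in-band tones", {
  fs <- 1000; t <- (0:1999) / fs
  e <- as_epochs(matrix(sin(2 * pi * 30 * t), 1), fs)
  d <- downsample(e, 100)
  expect_equal(d$fs, 100)
  expect_equal(dim(d$data)[3], 200)

  x <- d$data[1, 1, ]
  sp <- abs(stats::fft(x))[1:(length(x) / 2)]
  peak_hz <- (which.max(sp) - 1) * 100 / length(x)
  expect_equal(peak_hz, 30)

  expect_identical(downsample(e, fs), e)
  expect_error(downsample(e, 2000), "exceed")
})

test_that("epoch cropping keeps the half-open window", {
  e <- gen_mi_eeg_epochs(sim_config(n_trials = 2, n_channels = 4, fs = 100,
                                    duration = 4, seed = 5))
  c1 <- crop_epochs(e, 0.5, 3.5)
  expect_equal(dim(c1$data)[3], 300)
  expect_equal(c1$t0, 0.5)

  full <- crop_epochs(e, 0, 4)
  expect_equal(full$data, e$data)
  expect_error(crop_epochs(e, 1, 1), "strictly")
  expect_error(crop_epochs(e, 3, 5), "beyond")
})

test_that("CSP recovers the discriminative axes of a diagonal toy problem", {
  # class A per-trial channel variances (4, 1); class B (1, 4)
  set.seed(6)
  nt <- 20; ns <- 200
  data <- array(NA_real_, c(2 * nt, 2, ns))
  labels <- rep(c(1L, -1L), nt)
  for (i in seq_len(2 * nt)) {
    sds <- if (labels[i] == 1L) c(2, 1) else c(1, 2)
    data[i, , ] <- rbind(rnorm(ns, sd = sds[1]), rnorm(ns, sd = sds[2]))
  }
  e <- eeg_epochs(data, 100, labels)
  m <- fit_csp(e, n_pairs = 1)

  # top filter aligned with channel 1, bottom with channel 2 (up to sign)
  w_top <- m$filters[, 1] / sqrt(sum(m$filters[, 1]^2))
  w_bot <- m$filters[, 2] / sqrt(sum(m$filters[, 2]^2))
  expect_gt(abs(w_top[1]), 0.99)
  expect_gt(abs(w_bot[2]), 0.99)

  # normalization and joint diagonalization conventions
  Cc <- m$class_cov_a + m$class_cov_b
  expect_equal(crossprod(m$filters, Cc %*% m$filters), diag(2),
               tolerance = 1e-8)
  off <- function(M) max(abs(M - diag(diag(M))))
  expect_lt(off(crossprod(m$filters, m$class_cov_a %*% m$filters)), 1e-8)
  expect_lt(off(crossprod(m$filters, m$class_cov_b %*% m$filters)), 1e-8)
})

test_that("identical class distributions give eigenvalues near one half", {
  set.seed(8)
  e <- eeg_epochs(array(rnorm(40 * 4 * 100), c(40, 4, 100)), 100,
                  rep(c(1L, -1L), 20))
  m <- fit_csp(e, n_pairs = 2)
  expect_equal(m$eigenvalues, rep(0.5, 4), tolerance = 0.1)
})

test_that("log-variance features have the documented size and invariances", {
  e <- gen_mi_eeg_epochs(sim_config(n_trials = 10, n_channels = 12, seed = 9))
  m <- fit_csp(e, n_pairs = 5)
  f <- csp_features(m, e)
  expect_equal(ncol(f$X), 10)
  expect_equal(nrow(f$X), 20)

  # per-trial global gain leaves normalized log-variance unchanged
  e10 <- e; e10$data[3, , ] <- e10$data[3, , ] * 10
  f10 <- csp_features(m, e10)
  expect_equal(f10$X[3, ], f$X[3, ], tolerance = 1e-10)

  ez <- e; ez$data[1, , ] <- 0
  expect_error(csp_features(m, ez), "zero variance")
  expect_error(csp_features(m, gen_mi_eeg_epochs(
    sim_config(n_trials = 2, n_channels = 6, seed = 1))), "channel count")
})

test_that("deterministic front end: same input gives bit-identical features", {
  e <- gen_mi_eeg_epochs(sim_config(n_trials = 8, n_channels = 8, seed = 10))
  run <- function() {
    p <- preprocess_epochs(e, target_fs = NULL)
    m <- fit_csp(p, n_pairs = 2)
    csp_features(m, p)$X
  }
  expect_identical(run(), run())
})

test_that("strong ERD yields well-separated top-pair CSP features", {
  ok <- 0L
  for (s in 1:10) {
    e <- gen_mi_eeg_epochs(sim_config(n_trials = 30, n_channels = 8,
                                      erd_depth = 0.7, seed = 200 + s))
    p <- preprocess_epochs(e, target_fs = NULL)
    m <- fit_csp(p, n_pairs = 1)
    f <- csp_features(m, p)
    smd <- function(j) {
      a <- f$X[f$labels == 1L, j]; b <- f$X[f$labels == -1L, j]
      abs(mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
    }
    if (max(smd(1), smd(2)) > 1.0) ok <- ok + 1L
  }
  expect_gte(ok, 8L)
})
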