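# All generators draw from a local RNG stream seeded per call: the global
# .Random.seed is saved and restored, so no global state leaks.
.with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulation configuration for synthetic motor-imagery EEG
#'
#' Describes band-limited oscillatory EEG with class-dependent sensorimotor
#' power modulation. During imagined movement of one hand, the rhythm power
#' over the contralateral motor cortex drops (event-related
#' desynchronization, ERD); `erd_depth` is the fractional power reduction
#' of the 8-30 Hz rhythm in the attenuated channels (0 emulates a user with
#' no decodable modulation, values near 1 a strongly modulating user).
#'
#' @param n_trials Trials per class.
#' @param n_channels Channel count (default 20, named after the
#'   motor-cortex montage when 20).
#' @param fs Sampling rate in Hz.
#' @param duration Epoch length in seconds.
#' @param erd_channels Indices of channels attenuated during class `+1`
#'   (left-hand imagery attenuates the right hemisphere). Default: the
#'   right-lateralized half of the montage.
#' @param erd_channels_b Disjoint channel set attenuated during class `-1`.
#'   Default: the mirrored (left-lateralized) set.
#' @param erd_depth Fractional rhythm-power reduction in `[0, 1]`.
#' @param rhythm_sd Standard deviation (microvolts) of the unattenuated
#'   8-30 Hz rhythm.
#' @param noise_sd Standard deviation of the broadband noise floor.
#' @param seed RNG seed for this call.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_trials = 100L, n_channels = 20L, fs = 100,
                       duration = 4, erd_channels = NULL,
                       erd_channels_b = NULL, erd_depth = 0.7,
                       rhythm_sd = 2, noise_sd = 1, seed = 1L) {
  if (n_trials < 1L) stop("configuration error in `n_trials`: must be >= 1")
  if (n_channels < 2L) stop("configuration error in `n_channels`: must be >= 2")
  if (fs <= 0) stop("configuration error in `fs`: must be positive")
  if (duration <= 0) stop("configuration error in `duration`: must be positive")
  if (!is.numeric(erd_depth) || erd_depth < 0 || erd_depth > 1)
    stop("configuration error in `erd_depth`: must lie in [0, 1]")
  if (noise_sd < 0) stop("configuration error in `noise_sd`: must be >= 0")
  half <- floor(n_channels / 2)
  if (is.null(erd_channels))
    erd_channels <- seq_len(ceiling(half / 2)) + n_channels - ceiling(half / 2)
  if (is.null(erd_channels_b))
    erd_channels_b <- seq_len(ceiling(half / 2))
  erd_channels <- as.integer(erd_channels)
  erd_channels_b <- as.integer(erd_channels_b)
  if (any(erd_channels < 1L | erd_channels > n_channels))
    stop("configuration error in `erd_channels`: indices outside 1..n_channels")
  if (any(erd_channels_b < 1L | erd_channels_b > n_channels))
    stop("configuration error in `erd_channels_b`: indices outside 1..n_channels")
  if (length(intersect(erd_channels, erd_channels_b)))
    stop("configuration error: `erd_channels` and `erd_channels_b` must be disjoint")
  structure(list(n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels), fs = fs,
                 duration = duration, erd_channels = erd_channels,
                 erd_channels_b = erd_channels_b, erd_depth = erd_depth,
                 rhythm_sd = rhythm_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Source-to-target domain shift configuration
#'
#' Emulates between-session / between-subject non-stationarity: per-channel
#' gain drift (electrode impedance changes), additive sensor noise, and a
#' small orthogonal rotation mixing adjacent channels (electrode
#' repositioning). `mean_offset` applies only to the feature-level
#' generator [gen_feature_domains()].
#'
#' @param gain_drift Per-channel multiplicative gain, strictly positive;
#'   recycled to the channel count.
#' @param extra_noise_sd Additional white-noise standard deviation
#'   (microvolts).
#' @param mixing_rotation_angle Rotation angle in radians applied between
#'   adjacent channel pairs.
#' @param mean_offset Magnitude of the feature-space translation (for the
#'   feature-level generator).
#' @param seed RNG seed for the stochastic parts of the shift.
#' @return An object of class `shift_config`.
#' @export
shift_config <- function(gain_drift = 1, extra_noise_sd = 0,
                         mixing_rotation_angle = 0, mean_offset = 0,
                         seed = 1L) {
  if (any(gain_drift <= 0))
    stop("configuration error in `gain_drift`: must be strictly positive")
  if (extra_noise_sd < 0)
    stop("configuration error in `extra_noise_sd`: must be >= 0")
  structure(list(gain_drift = as.numeric(gain_drift),
                 extra_noise_sd = extra_noise_sd,
                 mixing_rotation_angle = mixing_rotation_angle,
                 mean_offset = mean_offset, seed = as.integer(seed)),
            class = "shift_config")
}

#' Generate synthetic motor-imagery EEG epochs
#'
#' Each trial is broadband Gaussian noise plus an independent band-limited
#' (8-30 Hz) rhythm on every channel, synthesized by passing white noise
#' through the package's own zero-phase Butterworth band-pass. For class
#' `+1` the rhythm amplitude in `erd_channels` is scaled by
#' `sqrt(1 - erd_depth)` (a power reduction by the factor `1 - erd_depth`);
#' for class `-1` the disjoint set `erd_channels_b` is attenuated instead.
#' Trials are generated in label-interleaved order with exactly `n_trials`
#' per class; output is deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @return Labeled [eeg_epochs()] with `2 * n_trials` trials.
#' @export
gen_mi_eeg_epochs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ns <- round(cfg$duration * cfg$fs)
  nt <- 2L * cfg$n_trials
  nc <- cfg$n_channels
  labels <- rep(c(1L, -1L), cfg$n_trials)
  bf <- .butter_bandpass(8, min(30, 0.45 * cfg$fs), 5L, cfg$fs)

  .with_local_seed(cfg$seed, {
    # rhythm: filtered white noise, rescaled per column to rhythm_sd
    raw <- matrix(stats::rnorm(ns * nt * nc), nrow = ns)
    raw <- .filtfilt_matrix(bf, raw)
    sds <- apply(raw, 2L, stats::sd)
    raw <- sweep(raw, 2L, sds / cfg$rhythm_sd, "/")
    rhythm <- aperm(array(raw, dim = c(ns, nt, nc)), c(2L, 3L, 1L))
    noise <- array(stats::rnorm(nt * nc * ns, sd = cfg$noise_sd),
                   dim = c(nt, nc, ns))

    att <- sqrt(1 - cfg$erd_depth)
    for (i in seq_len(nt)) {
      ch <- if (labels[i] == 1L) cfg$erd_channels else cfg$erd_channels_b
      rhythm[i, ch, ] <- rhythm[i, ch, ] * att
    }
    data <- rhythm + noise
    chn <- if (nc == 20L) motor_channels_20() else paste0("ch", seq_len(nc))
    eeg_epochs(data, cfg$fs, labels, chn, t0 = 0)
  })
}

#' Apply a domain shift to epochs
#'
#' Per-channel gains, an orthogonal rotation mixing adjacent channel pairs,
#' and additive white noise, in that order. Labels are preserved.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param shift A [shift_config()].
#' @return Shifted epochs with identical labels and channel names.
#' @export
apply_domain_shift <- function(epochs, shift) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(shift, "shift_config"))
  nc <- n_channels(epochs)
  gains <- shift$gain_drift
  if (length(gains) == 1L) gains <- rep(gains, nc)
  if (length(gains) != nc)
    stop(sprintf("gain vector length %d does not match %d channels",
                 length(gains), nc))
  R <- .adjacent_rotation(nc, shift$mixing_rotation_angle)
  d <- dim(epochs$data)
  out <- epochs$data
  identity_mix <- shift$mixing_rotation_angle == 0
  for (i in seq_len(d[1L])) {
    X <- out[i, , ] * gains
    if (!identity_mix) X <- R %*% X
    out[i, , ] <- X
  }
  if (shift$extra_noise_sd > 0) {
    out <- out + .with_local_seed(shift$seed,
      array(stats::rnorm(prod(d), sd = shift$extra_noise_sd), dim = d))
  }
  eeg_epochs(out, epochs$fs, epochs$labels, epochs$channel_names, epochs$t0)
}

# orthogonal rotation built from Givens rotations on adjacent index pairs
.adjacent_rotation <- function(n, angle) {
  R <- diag(n)
  if (angle == 0 || n < 2L) return(R)
  for (j in seq(1L, n - 1L, by = 2L)) {
    G <- diag(n)
    G[j, j] <- cos(angle); G[j + 1L, j + 1L] <- cos(angle)
    G[j, j + 1L] <- -sin(angle); G[j + 1L, j] <- sin(angle)
    R <- G %*% R
  }
  R
}

#' Generate a shifted source/target feature-domain pair
#'
#' Feature-level shortcut for testing the adaptation and classification
#' stages: two isotropic Gaussian classes per domain with means separated
#' by `class_sep` along a random unit direction; the target domain is drawn
#' from the source distribution and then composed with the shift (adjacent
#' dimension rotation, per-dimension gain, translation of magnitude
#' `mean_offset` along a random direction, extra noise). The target labels
#' are generated but held out of the target dataset; they are returned
#' separately for evaluation.
#'
#' @param n_s,n_t Per-class trial counts for source and target (>= 2).
#' @param dim Feature dimension (>= 2).
#' @param class_sep Distance between class means (>= 0).
#' @param shift A [shift_config()].
#' @param seed RNG seed.
#' @return A list with `source` (labeled [domain_dataset()]), `target`
#'   (unlabeled) and `target_labels`.
#' @export
gen_feature_domains <- function(n_s = 100L, n_t = 100L, dim = 10L,
                                class_sep = 3, shift = shift_config(),
                                seed = 1L) {
  if (dim < 2L) stop("configuration error in `dim`: must be >= 2")
  if (n_s < 2L || n_t < 2L)
    stop("configuration error: `n_s` and `n_t` must be >= 2 per class")
  if (class_sep < 0)
    stop("configuration error in `class_sep`: must be >= 0")
  stopifnot(inherits(shift, "shift_config"))

  .with_local_seed(seed, {
    u <- stats::rnorm(dim); u <- u / sqrt(sum(u^2))
    draw <- function(n_per_class) {
      lab <- rep(c(1L, -1L), n_per_class)
      X <- matrix(stats::rnorm(2L * n_per_class * dim), ncol = dim)
      X <- X + outer(lab, u) * (class_sep / 2)
      list(X = X, labels = lab)
    }
    src <- draw(n_s)
    tgt <- draw(n_t)

    gains <- shift$gain_drift
    if (length(gains) == 1L) gains <- rep(gains, dim)
    if (length(gains) != dim)
      stop("gain vector length does not match the feature dimension")
    R <- .adjacent_rotation(dim, shift$mixing_rotation_angle)
    v <- stats::rnorm(dim); v <- v / sqrt(sum(v^2))
    Xt <- sweep(tgt$X, 2L, gains, "*") %*% t(R)
    Xt <- Xt + matrix(v * shift$mean_offset, nrow(Xt), dim, byrow = TRUE)
    if (shift$extra_noise_sd > 0)
      Xt <- Xt + matrix(stats::rnorm(length(Xt), sd = shift$extra_noise_sd),
                        nrow(Xt))

    list(source = domain_dataset(src$X, src$labels, "source"),
         target = domain_dataset(Xt, NULL, "target"),
         target_labels = tgt$labels)
  })
}
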