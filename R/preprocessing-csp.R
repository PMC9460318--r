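#' Motor-cortex channel subset
#'
#' The 20 channels over the sensorimotor region used by the default
#' pipeline, in the 10/20 naming convention.
#'
#' @return Character vector of 20 channel names.
#' @export
motor_channels_20 <- function() {
  c("FC5", "FC3", "FC1", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6")
}

#' Select and reorder channels
#'
#' @param epochs An [eeg_epochs()] object.
#' @param names Channel names to keep, in the desired order (default: the
#'   20-channel motor-cortex subset of [motor_channels_20()]).
#' @return Epochs restricted to the requested channels.
#' @export
select_channels <- function(epochs, names = motor_channels_20()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- match(names, epochs$channel_names)
  if (anyNA(idx))
    stop("channel(s) not present: ",
         paste(names[is.na(idx)], collapse = ", "))
  eeg_epochs(epochs$data[, idx, , drop = FALSE], epochs$fs, epochs$labels,
             epochs$channel_names[idx], epochs$t0)
}

# zero-phase Butterworth bandpass of a single signal vector
.butter_bandpass <- function(low_hz, high_hz, order, fs) {
  signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

# direct-form IIR filter applied down the columns of a matrix (zero initial
# state), vectorized across columns; agrees with signal::filter per column
.iir_matrix <- function(b, a, X) {
  b <- b / a[1L]; a <- a / a[1L]
  nb <- length(b)
  Xp <- rbind(matrix(0, nb - 1L, ncol(X)), X)
  Z <- stats::filter(Xp, b, method = "convolution", sides = 1L)
  Z <- as.matrix(Z)[nb - 1L + seq_len(nrow(X)), , drop = FALSE]
  if (length(a) > 1L)
    Z <- as.matrix(stats::filter(Z, -a[-1L], method = "recursive"))
  Z
}

# zero-phase (forward-backward) filtering down matrix columns. The signal
# is extended at both ends by odd reflection, with the extension length set
# from the slowest filter pole so start-up transients decay inside the
# discarded padding.
.filtfilt_matrix <- function(filt, X) {
  b <- filt$b; a <- filt$a
  r <- max(Mod(polyroot(rev(a))))
  npad <- if (r < 1) ceiling(log(1e-12) / log(r)) else 3000L
  npad <- max(3L * max(length(a), length(b)), min(npad, 3000L))
  n <- nrow(X)
  k <- min(npad, n - 1L)
  top <- 2 * matrix(X[1L, ], k, ncol(X), byrow = TRUE) -
    X[seq(k + 1L, 2L), , drop = FALSE]
  bot <- 2 * matrix(X[n, ], k, ncol(X), byrow = TRUE) -
    X[seq(n - 1L, n - k), , drop = FALSE]
  Y <- .iir_matrix(b, a, rbind(top, X, bot))
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y <- .iir_matrix(b, a, Y)
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y[k + seq_len(n), , drop = FALSE]
}

# apply a signal filter forward-backward over the sample axis of an
# epochs array [trials x channels x samples]
.filtfilt_epochs <- function(data, filt) {
  d <- dim(data)
  m <- matrix(aperm(data, c(3L, 1L, 2L)), nrow = d[3L])
  m <- .filtfilt_matrix(filt, m)
  aperm(array(m, dim = c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
}

#' Band-pass filter epochs
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied per channel
#' and per trial; the effective magnitude response is the squared filter
#' response and no phase distortion is introduced. Defaults select the
#' 8-30 Hz sensorimotor band with a 5th-order design.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param order Butterworth order (default 5).
#' @return Filtered epochs.
#' @export
bandpass_filter <- function(epochs, low_hz = 8, high_hz = 30, order = 5L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!(0 < low_hz && low_hz < high_hz && high_hz < epochs$fs / 2))
    stop(sprintf("band [%g, %g] Hz must lie strictly inside (0, fs/2) = (0, %g)",
                 low_hz, high_hz, epochs$fs / 2))
  bf <- .butter_bandpass(low_hz, high_hz, order, epochs$fs)
  eeg_epochs(.filtfilt_epochs(epochs$data, bf), epochs$fs, epochs$labels,
             epochs$channel_names, epochs$t0)
}

#' Downsample epochs
#'
#' For an integer decimation factor, an 8th-order zero-phase Butterworth
#' low-pass at 80% of the new Nyquist frequency is applied first as the
#' anti-alias stage, then every k-th sample is kept. Non-integer ratios go
#' through polyphase resampling.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param target_fs New sampling rate in Hz; must not exceed `fs`.
#' @return Resampled epochs with `fs = target_fs`.
#' @export
downsample <- function(epochs, target_fs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (target_fs > epochs$fs)
    stop("`target_fs` must not exceed the current sampling rate")
  if (target_fs == epochs$fs) return(epochs)
  fs <- epochs$fs
  factor <- fs / target_fs
  d <- dim(epochs$data)
  if (abs(factor - round(factor)) < 1e-9) {
    factor <- round(factor)
    lp <- signal::butter(8L, 0.8 * (target_fs / 2) / (fs / 2), type = "low")
    filtered <- .filtfilt_epochs(epochs$data, lp)
    keep <- seq(1L, d[3L], by = factor)
    out <- filtered[, , keep, drop = FALSE]
  } else {
    p_q <- .rational_ratio(target_fs / fs)
    m <- matrix(aperm(epochs$data, c(3L, 1L, 2L)), nrow = d[3L])
    cols <- lapply(seq_len(ncol(m)), function(j)
      signal::resample(m[, j], p_q[1L], p_q[2L]))
    ns_new <- length(cols[[1L]])
    out <- aperm(array(unlist(cols), dim = c(ns_new, d[1L], d[2L])),
                 c(2L, 3L, 1L))
  }
  eeg_epochs(out, target_fs, epochs$labels, epochs$channel_names, epochs$t0)
}

.rational_ratio <- function(x, max_den = 1000L) {
  for (den in seq_len(max_den)) {
    num <- x * den
    if (abs(num - round(num)) < 1e-9) return(c(round(num), den))
  }
  stop("cannot express the resampling ratio as a small rational number")
}

#' Crop epochs to a time window
#'
#' Keeps samples whose time (relative to the cue, accounting for the epoch
#' origin `t0`) lies in the half-open interval `[t_start_s, t_end_s)`.
#' Defaults retain 0.5-3.5 s after the cue.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param t_start_s,t_end_s Window in seconds, `t_start_s < t_end_s`.
#' @return Cropped epochs with `t0 = t_start_s`.
#' @export
crop_epochs <- function(epochs, t_start_s = 0.5, t_end_s = 3.5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (t_start_s >= t_end_s) stop("`t_start_s` must be strictly before `t_end_s`")
  ns <- n_samples(epochs)
  t <- epochs$t0 + (seq_len(ns) - 1L) / epochs$fs
  keep <- which(t >= t_start_s - 1e-12 & t < t_end_s - 1e-12)
  if (!length(keep))
    stop("crop window lies outside the epoch")
  if (t_start_s < epochs$t0 - 1e-12 || t_end_s > epochs$t0 + ns / epochs$fs + 1e-12)
    stop(sprintf("crop window [%g, %g) s extends beyond the epoch [%g, %g) s",
                 t_start_s, t_end_s, epochs$t0, epochs$t0 + ns / epochs$fs))
  eeg_epochs(epochs$data[, , keep, drop = FALSE], epochs$fs, epochs$labels,
             epochs$channel_names, t0 = t_start_s)
}

# trial-normalized average class covariance: each trial's channel covariance
# is scaled to unit trace before averaging, so high-power trials do not
# dominate the estimate
.class_covariance <- function(data, trials) {
  nc <- dim(data)[2L]
  acc <- matrix(0, nc, nc)
  for (i in trials) {
    X <- data[i, , ]              # channels x samples
    C <- tcrossprod(X) / ncol(X)
    acc <- acc + C / sum(diag(C))
  }
  acc / length(trials)
}

#' Fit common spatial patterns
#'
#' Solves the generalized eigenproblem
#' \eqn{\Sigma_a w = \lambda (\Sigma_a + \Sigma_b) w} for the two class
#' covariances (class `+1` = a, class `-1` = b), with per-trial
#' trace-normalized covariance averaging and a ridge of
#' `1e-9 * trace` on the composite for conditioning. Filter columns are
#' sorted by descending eigenvalue and satisfy
#' \eqn{W^\top(\Sigma_a + \Sigma_b)W = I}, which jointly diagonalizes both
#' class covariances.
#'
#' @param epochs Labeled [eeg_epochs()] with both classes present.
#' @param n_pairs Number of filter pairs to retain at feature time
#'   (default 5, giving 10 features).
#' @return An object of class `csp_model` with `filters`, `eigenvalues`,
#'   `n_pairs` and the class covariances.
#' @export
fit_csp <- function(epochs, n_pairs = 5L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(epochs$labels)) stop("CSP requires labeled epochs")
  ia <- which(epochs$labels == 1L)
  ib <- which(epochs$labels == -1L)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("CSP requires at least 2 trials per class")
  nc <- n_channels(epochs)
  if (n_pairs < 1L || 2L * n_pairs > nc)
    stop("`n_pairs` must satisfy 1 <= 2*n_pairs <= n_channels")

  Ca <- .class_covariance(epochs$data, ia)
  Cb <- .class_covariance(epochs$data, ib)
  Cc <- Ca + Cb
  Cc <- Cc + diag(nc) * 1e-9 * sum(diag(Cc))

  R <- tryCatch(chol(Cc), error = function(e)
    stop("composite covariance is singular even after ridge regularization; ",
         "consider stronger regularization or more trials"))
  Rinv <- backsolve(R, diag(nc))
  S <- crossprod(Rinv, Ca %*% Rinv)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)     # eigenvalues descending
  W <- Rinv %*% es$vectors             # W' Cc W = I by construction

  structure(list(filters = W, eigenvalues = es$values,
                 n_pairs = as.integer(n_pairs),
                 class_cov_a = Ca, class_cov_b = Cb),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d channels, %d filter pairs retained\n",
              nrow(x$filters), x$n_pairs))
  cat("  leading eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 4L)), collapse = " "),
      "...\n")
  invisible(x)
}

#' CSP log-variance features
#'
#' Projects each trial onto the first and last `n_pairs` spatial filters
#' (the variance-ratio extremes for the two classes) and returns, per
#' retained filter, the log of its variance normalized by the trial's total
#' retained variance. The normalization makes the features invariant to a
#' per-trial global gain. With the default 5 pairs the feature vector is
#' 1 x 10.
#'
#' @param model A fitted `csp_model`.
#' @param epochs Epochs with the same channel count as at fit time.
#' @return A [domain_dataset()] (`role = "source"` when labels are present,
#'   else `"target"`), with `D = 2 * n_pairs` columns.
#' @export
csp_features <- function(model, epochs) {
  stopifnot(inherits(model, "csp_model"), inherits(epochs, "eeg_epochs"))
  nc <- n_channels(epochs)
  if (nc != nrow(model$filters))
    stop("channel count does not match the CSP model")
  np <- model$n_pairs
  sel <- c(seq_len(np), nc - np + seq_len(np))
  Ws <- model$filters[, sel, drop = FALSE]
  nt <- n_trials(epochs)
  F_out <- matrix(NA_real_, nt, 2L * np)
  for (i in seq_len(nt)) {
    Y <- crossprod(Ws, epochs$data[i, , ])   # (2*n_pairs) x samples
    v <- apply(Y, 1L, stats::var)
    if (any(v <= 0))
      stop(sprintf("trial %d has zero variance after spatial filtering; cannot form log-variance features", i))
    F_out[i, ] <- log(v / sum(v))
  }
  colnames(F_out) <- paste0("csp", seq_len(2L * np))
  domain_dataset(F_out, labels = epochs$labels,
                 role = if (is.null(epochs$labels)) "target" else "source")
}

#' Default preprocessing front end
#'
#' Channel subset (when the requested names are present), band-pass,
#' downsample, and epoch crop, in that order; the band-pass precedes the
#' downsampling so the retained 8-30 Hz band is already below the new
#' Nyquist frequency.
#'
#' @param epochs Raw [eeg_epochs()].
#' @param channels Channel subset (`NULL` to keep all).
#' @param low_hz,high_hz,order Band-pass settings.
#' @param target_fs Output sampling rate (`NULL` to keep).
#' @param t_start_s,t_end_s Crop window (`NULL` to skip cropping).
#' @return Preprocessed epochs.
#' @export
preprocess_epochs <- function(epochs, channels = NULL,
                              low_hz = 8, high_hz = 30, order = 5L,
                              target_fs = 100,
                              t_start_s = 0.5, t_end_s = 3.5) {
  if (!is.null(channels)) epochs <- select_channels(epochs, channels)
  epochs <- bandpass_filter(epochs, low_hz, high_hz, order)
  if (!is.null(target_fs) && target_fs != epochs$fs)
    epochs <- downsample(epochs, target_fs)
  if (!is.null(t_start_s) && !is.null(t_end_s))
    epochs <- crop_epochs(epochs, t_start_s, t_end_s)
  epochs
}
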