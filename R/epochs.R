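#' Epoched multichannel EEG
#'
#' Container for segmented (epoched) EEG: a numeric array of
#' `trials x channels x samples` in microvolts, together with the sampling
#' rate, channel names, per-trial class labels and the epoch start time
#' relative to the task cue.
#'
#' @param data Numeric array `[n_trials, n_channels, n_samples]` in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Integer vector of per-trial class labels in `{+1, -1}`
#'   (`+1` = left-hand motor imagery, `-1` = right-hand). May be `NULL` for
#'   unlabeled epochs.
#' @param channel_names Character vector of channel names, length
#'   `n_channels`.
#' @param t0 Epoch start relative to the cue, in seconds (default 0).
#'
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, labels = NULL, channel_names = NULL, t0 = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trials x channels x samples]")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  d <- dim(data)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(d[2L]))
  if (length(channel_names) != d[2L])
    stop("`channel_names` length must equal the number of channels")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != d[1L])
      stop("`labels` length must equal the number of trials")
    if (!all(labels %in% c(-1L, 1L)))
      stop("`labels` must be +1 or -1")
  }
  structure(
    list(data = data, fs = fs, labels = labels,
         channel_names = as.character(channel_names), t0 = t0),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  t0 = %g s, duration = %g s\n", x$t0, d[3L] / x$fs))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d of class +1, %d of class -1\n",
                sum(x$labels == 1L), sum(x$labels == -1L)))
  invisible(x)
}

n_trials   <- function(e) dim(e$data)[1L]
n_channels <- function(e) dim(e$data)[2L]
n_samples  <- function(e) dim(e$data)[3L]

#' Trial-feature dataset for one domain
#'
#' Row-per-trial feature matrix with optional labels and a domain role.
#' The source domain is labeled; the target domain is typically unlabeled
#' (labels, if present on a target, are used only for evaluation).
#'
#' @param X Numeric matrix `[n_trials x D]`.
#' @param labels Optional `+1/-1` label vector, length `n_trials`.
#' @param role `"source"` or `"target"`.
#'
#' @return An object of class `domain_dataset`.
#' @export
domain_dataset <- function(X, labels = NULL, role = c("source", "target")) {
  role <- match.arg(role)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("feature matrix contains non-finite values")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(X))
      stop("`labels` length must equal nrow(X)")
    if (!all(labels %in% c(-1L, 1L))) stop("`labels` must be +1 or -1")
  }
  if (role == "source" && is.null(labels))
    stop("a source domain must be labeled")
  structure(list(X = X, labels = labels, role = role),
            class = "domain_dataset")
}

#' @export
print.domain_dataset <- function(x, ...) {
  cat(sprintf("<domain_dataset role=%s> %d trials x %d features%s\n",
              x$role, nrow(x$X), ncol(x$X),
              if (is.null(x$labels)) " (unlabeled)" else " (labeled)"))
  invisible(x)
}

#' Save / load epochs
#'
#' Epochs are serialized to a single-file container with named members
#' (`data`, `fs`, `labels`, `channel_names`, `t0`); loading round-trips
#' bit-exactly.
#'
#' @param epochs An `eeg_epochs` object.
#' @param path File path.
#' @return `load_epochs` returns the restored `eeg_epochs`.
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  saveRDS(unclass(epochs), path, version = 3L)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot parse epochs container '",
                                           path, "': ", conditionMessage(e)))
  need <- c("data", "fs", "channel_names")
  if (!is.list(obj) || !all(need %in% names(obj)))
    stop("unsupported epochs file format; expected members data/fs/channel_names ",
         "(supported formats: .rds epochs container)")
  eeg_epochs(obj$data, obj$fs, obj$labels, obj$channel_names,
             if (is.null(obj$t0)) 0 else obj$t0)
}

#' Write / read a feature matrix as CSV
#'
#' Plain CSV with header `f1..fD,label`; the label column is omitted for
#' unlabeled datasets.
#'
#' @param dataset A `domain_dataset`.
#' @param path CSV path.
#' @param role Domain role to assign when reading.
#' @return `read_feature_csv` returns a `domain_dataset`.
#' @export
write_feature_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "domain_dataset"))
  df <- as.data.frame(dataset$X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  if (!is.null(dataset$labels)) df$label <- dataset$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path, role = c("source", "target")) {
  role <- match.arg(role)
  df <- utils::read.csv(path)
  has_lab <- "label" %in% names(df)
  X <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  domain_dataset(X, labels = if (has_lab) df$label else NULL, role = role)
}
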