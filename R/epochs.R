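#' Construct an epoch set
#'
#' The central container of the package: a `trials x channels x samples`
#' array of voltages (microvolts) with per-trial labels and a common time
#' axis in seconds relative to stimulus onset.
#'
#' @param data Numeric array, `trials x channels x samples`.
#' @param labels Character vector of per-trial labels (stimulus categories or
#'   decoding conditions), length `trials`.
#' @param times Numeric vector of sample times in seconds (0 = onset),
#'   length `samples`.
#' @param rate Sampling rate, Hz.
#' @param channels Character vector of channel names, length `channels`.
#' @param metadata Optional list (provenance log, simulation ground truth,
#'   rejection report, ...).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, times, rate, channels = NULL,
                      metadata = list()) {
  data <- unclass(data)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(dim(data)[2]))
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1]) stop("one label per trial required", call. = FALSE)
  if (length(times) != dim(data)[3]) stop("`times` must match sample count", call. = FALSE)
  if (length(channels) != dim(data)[2]) stop("`channels` must match channel count", call. = FALSE)
  stopifnot(rate > 0)
  if (anyNA(data)) stop("epoch data must not contain NA", call. = FALSE)
  structure(
    list(data = data, labels = labels, times = as.numeric(times),
         rate = rate, channels = as.character(channels), metadata = metadata),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "epoch_set: %d trials x %d channels x %d samples @ %g Hz, t in [%.3f, %.3f] s\n",
    n_trials(x), n_channels(x), n_samples(x), x$rate,
    min(x$times), max(x$times)
  ))
  cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Epoch set dimensions
#' @param x An `epoch_set`.
#' @return An integer count.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' @rdname n_trials
#' @export
n_channels <- function(x) dim(x$data)[2]

#' @rdname n_trials
#' @export
n_samples <- function(x) dim(x$data)[3]

#' Subset an epoch set by trial
#'
#' @param epochs An `epoch_set`.
#' @param idx Trial indices (integer or logical).
#' @return An `epoch_set` with the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
            epochs$times, epochs$rate, epochs$channels, epochs$metadata)
}

#' Temporally decimate an epoch set
#'
#' Keeps every `factor`-th sample starting at the first. Intended for data
#' already low-pass filtered well below the decimated Nyquist (the standard
#' 0.1-40 Hz band leaves a 1024 Hz recording safe to decimate by 4 to 256 Hz).
#'
#' @param epochs An `epoch_set`.
#' @param factor Positive integer decimation factor; 1 is a no-op.
#' @return The decimated `epoch_set`.
#' @export
decimate_epochs <- function(epochs, factor) {
  stopifnot(inherits(epochs, "epoch_set"), factor >= 1, factor == round(factor))
  if (factor == 1) return(epochs)
  keep <- seq(1L, n_samples(epochs), by = factor)
  epoch_set(epochs$data[, , keep, drop = FALSE], epochs$labels,
            epochs$times[keep], epochs$rate / factor, epochs$channels,
            epochs$metadata)
}

#' Write or read the package epoch container
#'
#' A directory holding `epochs.json` (metadata: dimensions, labels, channel
#' names, time axis, sampling rate, units, provenance) and `epochs.bin`
#' (little-endian float32, sample-fastest layout: for each trial, for each
#' channel, the samples in order; units microvolts).
#'
#' @param epochs An `epoch_set`.
#' @param dir Directory path (created if needed).
#' @return `read_epochs()` returns the `epoch_set`; `write_epochs()` returns
#'   `dir` invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "topodecode-epochs-v1",
    units = "microvolt",
    n_trials = n_trials(epochs), n_channels = n_channels(epochs),
    n_samples = n_samples(epochs),
    layout = "trials x channels x samples, sample-fastest",
    dtype = "float32le",
    rate = epochs$rate, times = epochs$times,
    labels = epochs$labels, channels = epochs$channels,
    metadata = epochs$metadata
  )
  jsonlite::write_json(meta, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(dir, "epochs.bin"), "wb")
  on.exit(close(con))
  # aperm -> samples vary fastest within channel within trial
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con,
           size = 4L, endian = "little")
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "epochs.json"),
                              simplifyVector = TRUE)
  n <- meta$n_trials * meta$n_channels * meta$n_samples
  con <- file(file.path(dir, "epochs.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  arr <- aperm(array(raw, dim = c(meta$n_samples, meta$n_channels, meta$n_trials)),
               c(3, 2, 1))
  md <- meta$metadata
  if (is.null(md)) md <- list()
  epoch_set(arr, meta$labels, meta$times, meta$rate, meta$channels, md)
}
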