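#' Construct a continuous EEG recording
#'
#' @param data Numeric `channels x samples` matrix, microvolts.
#' @param rate Sampling rate, Hz.
#' @param channels Channel names.
#' @return An object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(data, rate, channels = NULL) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(nrow(data)))
  stopifnot(rate > 0, length(channels) == nrow(data))
  if (anyNA(data)) stop("continuous EEG must not contain NA", call. = FALSE)
  structure(list(data = data, rate = rate, channels = as.character(channels)),
            class = "continuous_eeg")
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("continuous_eeg: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies the standard clinical AEP front end: each channel is demeaned,
#' band-pass filtered between `low` and `high` Hz and notch filtered at
#' `notch` Hz. The band-pass is realized as cascaded 2nd-order Butterworth
#' high- and low-pass sections and the notch as a biquad (Q = 35); every
#' section runs forward-backward ([signal::filtfilt()]), so the filtering is
#' zero-phase and the effective magnitude order doubles.
#'
#' @param eeg A [continuous_eeg()].
#' @param low,high Band-pass corner frequencies, Hz (defaults 0.1 and 40).
#' @param notch Notch frequency, Hz (default 50; `NULL` disables).
#' @return The filtered `continuous_eeg` (same length as the input).
#' @export
bandpass_notch <- function(eeg, low = 0.1, high = 40, notch = 50) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  nyq <- eeg$rate / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high", call. = FALSE)
  if (high >= nyq) stop("`high` must be below the Nyquist frequency", call. = FALSE)
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(2, high / nyq, type = "low")
  nt <- if (!is.null(notch)) notch_biquad(notch, eeg$rate, q = 35)
  out <- eeg$data
  for (i in seq_len(nrow(out))) {
    x <- out[i, ] - mean(out[i, ])
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    if (!is.null(nt)) x <- signal::filtfilt(nt, x)
    out[i, ] <- x
  }
  continuous_eeg(out, eeg$rate, eeg$channels)
}

# 2nd-order IIR notch (Audio EQ cookbook form).
notch_biquad <- function(f0, rate, q = 35) {
  w0 <- 2 * pi * f0 / rate
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + al, -2 * cos(w0), 1 - al)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Extract peri-stimulus epochs from a continuous recording
#'
#' Cuts one epoch per schedule event on the half-open time window
#' `[tmin, tmax)` relative to the event onset sample. Sample indices are
#' rounded half away from zero, so the default window at 1024 Hz spans 922
#' samples (indices -102..819 around onset). No baseline correction is
#' applied. Events whose window exceeds the recording are skipped with a
#' warning and logged in the metadata.
#'
#' @param eeg A [continuous_eeg()].
#' @param events A `session_schedule` or data frame with `onset_sample`
#'   (1-based) and `category` columns.
#' @param tmin,tmax Epoch window in seconds around onset.
#' @return An [epoch_set()] labelled by event category.
#' @export
extract_epochs <- function(eeg, events, tmin = -0.1, tmax = 0.8) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  idx <- epoch_index_grid(tmin, tmax, eeg$rate)
  times <- idx / eeg$rate
  ns_rec <- ncol(eeg$data)
  onset <- events$onset_sample
  ok <- (onset + idx[1] >= 1) & (onset + idx[length(idx)] <= ns_rec)
  skipped <- which(!ok)
  if (length(skipped) > 0) {
    warning(sprintf("%d event(s) too close to the recording edge were skipped",
                    length(skipped)), call. = FALSE)
  }
  keep <- which(ok)
  data <- array(0, dim = c(length(keep), nrow(eeg$data), length(idx)))
  for (j in seq_along(keep)) {
    data[j, , ] <- eeg$data[, onset[keep[j]] + idx]
  }
  epoch_set(data, events$category[keep], times, eeg$rate, eeg$channels,
            metadata = list(
              log = sprintf("epoched [%g, %g) s; %d events, %d skipped",
                            tmin, tmax, length(onset), length(skipped)),
              skipped_events = skipped
            ))
}

#' Reject trials exceeding an amplitude threshold
#'
#' A trial is removed when any channel at any sample exceeds
#' `threshold` microvolts in absolute value (the clinical +/- 100 uV
#' criterion by default; a single exceedance drops the whole trial).
#'
#' @param epochs An [epoch_set()].
#' @param threshold Absolute amplitude threshold, microvolts (> 0).
#' @return A list with `epochs` (accepted trials) and `report`, a data frame
#'   of per-condition totals, rejected counts and fractions; rejected trial
#'   indices are kept in `epochs$metadata$rejected_trials`.
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "epoch_set"), threshold > 0)
  nt <- n_trials(epochs)
  exceeds <- vapply(seq_len(nt), function(i) {
    max(abs(epochs$data[i, , ])) > threshold
  }, logical(1))
  conds <- sort(unique(epochs$labels))
  report <- data.frame(
    condition = conds,
    n_total = vapply(conds, function(cn) sum(epochs$labels == cn), integer(1)),
    n_rejected = vapply(conds, function(cn) {
      sum(exceeds & epochs$labels == cn)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  report$fraction <- report$n_rejected / report$n_total
  dead <- report$condition[report$n_rejected == report$n_total]
  if (length(dead) > 0) {
    stop(sprintf("all trials rejected for condition(s): %s",
                 paste(dead, collapse = ", ")), call. = FALSE)
  }
  kept <- subset_trials(epochs, !exceeds)
  kept$metadata$rejected_trials <- which(exceeds)
  kept$metadata$rejection_threshold <- threshold
  list(epochs = kept, report = report)
}

#' Split accepted trials into cross-validation and validation sets
#'
#' Maps raw labels onto the two decoding conditions given by
#' `condition_pair`, then assigns exactly `n_cv` trials per condition to the
#' cross-validation (CV) set uniformly at random without replacement; the
#' remaining accepted trials form the validation (V) set. A recording whose
#' conditions cannot supply `n_cv` CV trials plus at least one V trial is
#' excluded with an error, mirroring the clinical exclusion rule (fewer than
#' 60 artifact-free trials).
#'
#' @param epochs An [epoch_set()] of accepted trials.
#' @param condition_pair Named list of two character vectors; names are the
#'   decoding conditions, values the raw labels mapped to each, e.g.
#'   `list(animal = "animal", human = "human")` or
#'   `list(living = c("animal", "human"), manmade = "manmade")`.
#' @param n_cv CV trials per condition (default 60).
#' @param seed Integer seed for the random assignment.
#' @return An object of class `split_result`: list with `cv` and `v`
#'   ([epoch_set()]s labelled by condition), `seed`, `n_cv_per_condition`,
#'   and the selected trial `indices`.
#' @export
split_cv_validation <- function(epochs, condition_pair, n_cv = 60, seed) {
  stopifnot(inherits(epochs, "epoch_set"), n_cv >= 1,
            is.list(condition_pair), length(condition_pair) == 2,
            !is.null(names(condition_pair)))
  cond_of <- rep(NA_character_, n_trials(epochs))
  for (cn in names(condition_pair)) {
    cond_of[epochs$labels %in% condition_pair[[cn]]] <- cn
  }
  cv_idx <- v_idx <- integer(0)
  with_seed(seed, {
    for (cn in names(condition_pair)) {
      pool <- which(cond_of == cn)
      if (length(pool) < n_cv + 1) {
        stop(sprintf(
          "recording excluded: condition \"%s\" has %d accepted trials (requires %d CV + >= 1 V)",
          cn, length(pool), n_cv), call. = FALSE)
      }
      take <- sample(pool, n_cv)
      cv_idx <- c(cv_idx, take)
      v_idx <- c(v_idx, setdiff(pool, take))
    }
  })
  n_v <- vapply(names(condition_pair), function(cn) {
    sum(cond_of[v_idx] == cn)
  }, integer(1))
  if (any(n_v < 20)) {
    warning(sprintf("validation set has fewer than 20 trials for: %s",
                    paste(names(n_v)[n_v < 20], collapse = ", ")),
            call. = FALSE)
  }
  relabel <- function(idx) {
    out <- subset_trials(epochs, idx)
    out$labels <- cond_of[idx]
    out
  }
  structure(
    list(cv = relabel(cv_idx), v = relabel(v_idx), seed = seed,
         n_cv_per_condition = n_cv,
         indices = list(cv = cv_idx, v = v_idx)),
    class = "split_result"
  )
}
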