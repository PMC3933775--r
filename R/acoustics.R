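#' Binned power spectrogram (non-overlapping, zero-padded)
#'
#' Splits the waveform into non-overlapping rectangular windows of
#' `win_ms` milliseconds, zero-pads each to `round(rate / bin_hz)` samples
#' and takes the squared FFT magnitude. Power is one-sided and normalized so
#' that the sum over frequency bins of one time bin equals the window energy
#' (Parseval). The defaults give the 5 ms x 74 Hz grid used for the
#' stimulus-control comparisons.
#'
#' @param wave Numeric waveform.
#' @param rate Sampling rate, Hz.
#' @param win_ms Time bin width, milliseconds.
#' @param bin_hz Frequency bin width, Hz (sets the zero-padded FFT length).
#' @return An object of class `spectrogram`: `power`
#'   (`time_bins x freq_bins`), `times` (window centres, s), `freqs` (Hz),
#'   `rate`, `win_len`, `nfft`.
#' @export
spectrogram <- function(wave, rate, win_ms = 5, bin_hz = 74) {
  stopifnot(rate > 0, win_ms > 0, bin_hz > 0)
  wave <- as.numeric(wave)
  L <- as.integer(round_half_away(win_ms * rate / 1000))
  if (length(wave) < L) stop("waveform shorter than one window", call. = FALSE)
  nfft <- as.integer(round_half_away(rate / bin_hz))
  if (nfft < L) stop("`bin_hz` too wide: FFT length below the window length", call. = FALSE)
  n_win <- length(wave) %/% L
  seg <- matrix(0, nfft, n_win)
  seg[seq_len(L), ] <- wave[seq_len(L * n_win)]
  spec <- stats::mvfft(seg)
  n_keep <- nfft %/% 2L + 1L
  coef <- rep(2, n_keep)
  coef[1] <- 1
  if (nfft %% 2L == 0L) coef[n_keep] <- 1
  power <- t(coef * abs(spec[seq_len(n_keep), , drop = FALSE])^2 / nfft)
  structure(
    list(power = power,
         times = (seq_len(n_win) - 0.5) * L / rate,
         freqs = (seq_len(n_keep) - 1) * rate / nfft,
         rate = rate, win_len = L, nfft = nfft,
         win_ms = win_ms, bin_hz = rate / nfft),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("spectrogram: %d time bins x %d freq bins (%.3g ms x %.3g Hz)\n",
              nrow(x$power), ncol(x$power), 1000 * x$win_len / x$rate, x$bin_hz))
  invisible(x)
}

#' Time-averaged power spectrum of a spectrogram
#'
#' @param spec A [spectrogram()].
#' @return Numeric vector of mean power per frequency bin, with attribute
#'   `freqs`.
#' @export
power_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  out <- colMeans(spec$power)
  attr(out, "freqs") <- spec$freqs
  out
}

as_bin_matrix <- function(x) {
  if (inherits(x, "spectrogram")) return(x$power)
  if (is.matrix(x)) return(x)
  matrix(as.numeric(x), nrow = 1)  # 1-D spectrum as a single row
}

#' Bootstrap bin-wise comparison of two spectrogram groups
#'
#' Per time-frequency bin, the observed statistic (difference of group mean
#' power by default, Welch t optionally) is compared against an empirical
#' null built by resampling the pooled spectrograms with replacement into
#' pseudo-groups of the original sizes, `n_boot` times; the two-tailed
#' p-value is `(1 + #{|null| >= |observed|}) / (n_boot + 1)`. Bins with
#' `p < alpha` form the raw mask; the spatial mask additionally requires all
#' eight immediate neighbours to reach `p < alpha` (3 x 3 criterion; for 1-D
#' inputs, both line neighbours), so border bins are never spatially
#' flagged.
#'
#' @param group1,group2 Lists of [spectrogram()]s (or matrices / 1-D
#'   spectra) of identical shape; at least 2 per group.
#' @param n_boot Bootstrap iterations (default 5000).
#' @param alpha Per-bin significance level (default 0.05).
#' @param seed Integer seed.
#' @param statistic `"meandiff"` (default) or `"t"` (Welch t per bin).
#' @return An object of class `bin_test_result`: `observed_diff`, `p`,
#'   `raw_mask`, `spatial_mask` (same shape as one input), `n_boot`,
#'   `alpha`, `statistic`, `seed`.
#' @export
bootstrap_bin_test <- function(group1, group2, n_boot = 5000, alpha = 0.05,
                               seed = NULL, statistic = c("meandiff", "t")) {
  statistic <- match.arg(statistic)
  m1 <- lapply(group1, as_bin_matrix)
  m2 <- lapply(group2, as_bin_matrix)
  n1 <- length(m1); n2 <- length(m2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 members", call. = FALSE)
  shp <- dim(m1[[1]])
  all_m <- c(m1, m2)
  if (!all(vapply(all_m, function(m) identical(dim(m), shp), logical(1)))) {
    stop("all spectrograms must share the same shape", call. = FALSE)
  }
  G <- t(vapply(all_m, as.numeric, numeric(prod(shp))))
  i1 <- seq_len(n1)
  i2 <- n1 + seq_len(n2)

  stat_fun <- if (statistic == "meandiff") {
    function(a, b) colMeans(a) - colMeans(b)
  } else {
    function(a, b) {
      va <- apply(a, 2, var) / nrow(a)
      vb <- apply(b, 2, var) / nrow(b)
      (colMeans(a) - colMeans(b)) / sqrt(pmax(va + vb, .Machine$double.eps))
    }
  }
  obs <- stat_fun(G[i1, , drop = FALSE], G[i2, , drop = FALSE])
  abs_obs <- abs(obs)
  cnt <- integer(length(obs))
  with_seed(seed, {
    n <- n1 + n2
    for (r in seq_len(n_boot)) {
      a <- G[sample.int(n, n1, replace = TRUE), , drop = FALSE]
      b <- G[sample.int(n, n2, replace = TRUE), , drop = FALSE]
      cnt <- cnt + (abs(stat_fun(a, b)) >= abs_obs)
    }
  })
  p <- (1 + cnt) / (n_boot + 1)
  raw <- p < alpha
  pm <- matrix(p, shp[1], shp[2])
  spatial <- if (shp[1] == 1 || shp[2] == 1) {
    line_threshold(as.numeric(pm), alpha)
  } else {
    spatial_threshold(pm, alpha)
  }
  to_shape <- function(v) {
    out <- matrix(v, shp[1], shp[2])
    if (shp[1] == 1) as.numeric(out) else out
  }
  shape_l <- function(v) {
    out <- matrix(v, shp[1], shp[2])
    if (shp[1] == 1) as.logical(out) else out
  }
  structure(
    list(observed_diff = to_shape(obs), p = to_shape(p),
         raw_mask = shape_l(raw),
         spatial_mask = if (shp[1] == 1) as.logical(spatial) else spatial,
         n_boot = as.integer(n_boot), alpha = alpha, statistic = statistic,
         seed = seed),
    class = "bin_test_result"
  )
}

#' @export
print.bin_test_result <- function(x, ...) {
  cat(sprintf(
    "bin_test_result: %d/%d bins p < %g raw, %d after the spatial criterion (%d bootstrap iterations)\n",
    sum(x$raw_mask), length(x$p), x$alpha, sum(x$spatial_mask), x$n_boot))
  invisible(x)
}

#' 3 x 3 spatial threshold on a p-value grid
#'
#' A bin is flagged only if itself and all eight immediately adjacent bins
#' have `p < alpha`; border bins, whose neighbourhood is incomplete, are
#' never flagged.
#'
#' @param p Matrix of p-values, at least 3 x 3.
#' @param alpha Per-bin level.
#' @return Logical matrix of the same shape.
#' @export
spatial_threshold <- function(p, alpha) {
  if (!is.matrix(p) || nrow(p) < 3 || ncol(p) < 3) {
    stop("`p` must be a matrix of at least 3 x 3", call. = FALSE)
  }
  ok <- p < alpha
  out <- matrix(FALSE, nrow(p), ncol(p))
  ri <- 2:(nrow(p) - 1)
  ci <- 2:(ncol(p) - 1)
  acc <- matrix(TRUE, length(ri), length(ci))
  for (dr in -1:1) for (dc in -1:1) {
    acc <- acc & ok[ri + dr, ci + dc, drop = FALSE]
  }
  out[ri, ci] <- acc
  out
}

# 1-D analogue: a bin and both line neighbours below alpha; ends never flag.
line_threshold <- function(p, alpha) {
  n <- length(p)
  if (n < 3) stop("`p` must have at least 3 bins", call. = FALSE)
  ok <- p < alpha
  out <- logical(n)
  out[2:(n - 1)] <- ok[2:(n - 1)] & ok[1:(n - 2)] & ok[3:n]
  out
}

#' Harmonics-to-noise ratio of a waveform
#'
#' Framewise (30 ms frames, 10 ms hop) maximum of the normalized
#' autocorrelation over the lag range corresponding to `f0_range`,
#' converted to dB as `10 log10(r / (1 - r))` and averaged over voiced
#' frames (`r > 0`). Periodic sounds score high (r near 1), noise scores
#' near or below 0 dB.
#'
#' @param wave Numeric waveform (non-silent).
#' @param rate Sampling rate, Hz.
#' @param f0_range Candidate fundamental range, Hz (default 50-500).
#' @return Mean HNR in dB.
#' @export
hnr <- function(wave, rate, f0_range = c(50, 500)) {
  wave <- as.numeric(wave)
  if (all(wave == 0)) stop("`wave` is silent", call. = FALSE)
  stopifnot(length(f0_range) == 2, f0_range[1] > 0, f0_range[1] < f0_range[2])
  L <- as.integer(round_half_away(0.03 * rate))
  hop <- as.integer(round_half_away(0.01 * rate))
  lmin <- max(1L, as.integer(floor(rate / f0_range[2])))
  lmax <- as.integer(ceiling(rate / f0_range[1]))
  if (lmax >= L) stop("frame too short for the requested `f0_range`", call. = FALSE)
  starts <- seq(1L, length(wave) - L + 1L, by = hop)
  if (length(starts) == 0) stop("waveform shorter than one frame", call. = FALSE)
  rs <- vapply(starts, function(s) {
    x <- wave[s:(s + L - 1L)]
    if (sum(x^2) == 0) return(0)
    best <- 0
    for (l in lmin:lmax) {
      a <- x[1:(L - l)]
      b <- x[(l + 1):L]
      den <- sqrt(sum(a^2) * sum(b^2))
      if (den > 0) best <- max(best, sum(a * b) / den)
    }
    best
  }, numeric(1))
  rs <- rs[rs > 0]
  if (length(rs) == 0) return(-60)
  rs <- pmin(pmax(rs, 1e-6), 1 - 1e-6)
  mean(10 * log10(rs / (1 - rs)))
}
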