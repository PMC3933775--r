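#' Specify a synthetic test sound
#'
#' Minimal parametric stimuli for exercising the acoustic-control
#' statistics: harmonic complexes (vocalization-like, high
#' harmonics-to-noise ratio), white-noise bursts (man-made-object-like), and
#' silence.
#'
#' @param kind `"harmonic"`, `"noise_burst"` or `"silence"`.
#' @param f0 Fundamental frequency, Hz (harmonic kind).
#' @param n_harmonics Number of harmonics (harmonic kind).
#' @param jitter Fractional frequency jitter applied independently to each
#'   harmonic (0 = exactly periodic).
#' @param duration Duration, seconds (> 0).
#' @param rate Sampling rate, Hz.
#' @return An object of class `sound_spec`.
#' @export
sound_spec <- function(kind = c("harmonic", "noise_burst", "silence"),
                       f0 = 220, n_harmonics = 8, jitter = 0,
                       duration = 0.5, rate = 22500) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (kind == "harmonic" && f0 <= 0) stop("`f0` must be positive", call. = FALSE)
  stopifnot(rate > 0, n_harmonics >= 1, jitter >= 0)
  structure(list(kind = kind, f0 = f0, n_harmonics = n_harmonics,
                 jitter = jitter, duration = duration, rate = rate),
            class = "sound_spec")
}

#' Synthesize a test sound
#'
#' Harmonic sounds are sums of `n_harmonics` sinusoids at `k * f0` with
#' random phases, 1/k amplitude roll-off and optional fractional frequency
#' jitter; noise bursts are white noise; both get 10 ms cosine onset/offset
#' ramps and are normalized to unit root-mean-square amplitude, the same
#' normalization applied to the experiment's stimuli. Silence is returned
#' as zeros (no normalization is possible).
#'
#' @param spec A [sound_spec()].
#' @param seed Integer seed (phases, jitter, noise).
#' @return Numeric waveform vector with attribute `rate`.
#' @export
synth_sound <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sound_spec"))
  n <- as.integer(round_half_away(spec$duration * spec$rate))
  if (n < 1) stop("duration too short for one sample", call. = FALSE)
  t <- (seq_len(n) - 1) / spec$rate
  wave <- with_seed(seed, {
    switch(spec$kind,
      harmonic = {
        k <- seq_len(spec$n_harmonics)
        fk <- k * spec$f0 * (1 + spec$jitter * runif(length(k), -1, 1))
        ph <- runif(length(k), 0, 2 * pi)
        rowSums(sapply(seq_along(k), function(j) {
          sin(2 * pi * fk[j] * t + ph[j]) / k[j]
        }))
      },
      noise_burst = rnorm(n),
      silence = numeric(n)
    )
  })
  if (spec$kind != "silence") {
    ramp <- min(n %/% 2, as.integer(round_half_away(0.01 * spec$rate)))
    if (ramp > 1) {
      r <- 0.5 * (1 - cos(pi * (seq_len(ramp) - 1) / (ramp - 1)))
      wave[seq_len(ramp)] <- wave[seq_len(ramp)] * r
      wave[(n - ramp + 1):n] <- wave[(n - ramp + 1):n] * rev(r)
    }
    wave <- wave / sqrt(mean(wave^2))
  }
  attr(wave, "rate") <- spec$rate
  wave
}

#' Read or write a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE support covering the uncompressed 16-bit PCM files the
#' stimulus set uses. Samples are scaled to `[-1, 1)`.
#'
#' @param path File path.
#' @param wave Numeric vector (mono) or `channels x samples` matrix with
#'   values in `[-1, 1]`.
#' @param rate Sampling rate, Hz.
#' @return `read_wav()` returns a list with `wave` (vector or
#'   `channels x samples` matrix) and `rate`; `write_wav()` returns `path`
#'   invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file", call. = FALSE)
  }
  fmt <- NULL
  dat <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        format = readBin(con, "integer", 1L, size = 2L, endian = "little"),
        channels = readBin(con, "integer", 1L, size = 2L, endian = "little"),
        rate = readBin(con, "integer", 1L, size = 4L, endian = "little"),
        byte_rate = readBin(con, "integer", 1L, size = 4L, endian = "little"),
        block_align = readBin(con, "integer", 1L, size = 2L, endian = "little"),
        bits = readBin(con, "integer", 1L, size = 2L, endian = "little")
      )
      if (sz > 16) invisible(readBin(con, "raw", sz - 16L))
    } else if (id == "data") {
      dat <- readBin(con, "integer", n = sz %/% 2L, size = 2L,
                     signed = TRUE, endian = "little")
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("incomplete WAV file", call. = FALSE)
  if (fmt$format != 1L || fmt$bits != 16L) {
    stop("only 16-bit PCM WAV is supported", call. = FALSE)
  }
  wave <- dat / 32768
  if (fmt$channels > 1L) {
    wave <- matrix(wave, nrow = fmt$channels)  # samples are interleaved
  }
  list(wave = wave, rate = fmt$rate)
}

#' @rdname read_wav
#' @export
write_wav <- function(wave, rate, path) {
  if (is.matrix(wave)) {
    nch <- nrow(wave)
    samples <- as.numeric(wave)  # column-major = interleaved frames
  } else {
    nch <- 1L
    samples <- as.numeric(wave)
  }
  pcm <- as.integer(round_half_away(pmax(-1, pmin(samples, 32767 / 32768)) * 32768))
  data_size <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  wr_int <- function(x, size) writeBin(as.integer(x), con, size = size,
                                       endian = "little")
  writeChar("RIFF", con, eos = NULL); wr_int(36L + data_size, 4L)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr_int(16L, 4L)
  wr_int(1L, 2L); wr_int(nch, 2L); wr_int(rate, 4L)
  wr_int(rate * nch * 2L, 4L); wr_int(nch * 2L, 2L); wr_int(16L, 2L)
  writeChar("data", con, eos = NULL); wr_int(data_size, 4L)
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
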