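#' Configure the synthetic EEG generator
#'
#' Describes the generative model for simulated single-trial epochs: a
#' stimulus-locked component common to all trials (an evoked response), an
#' optional condition-specific topographic effect confined to a time window,
#' spatially correlated Gaussian noise, and an amplitude-artifact process.
#' Defaults emulate a 19-channel 10-20 recording at 1024 Hz with an
#' N100-like fronto-central component and realistic single-trial noise.
#'
#' @param n_channels Channel count; 19 uses the built-in 10-20 names.
#' @param channels Channel names; defaults to the 10-20 montage for 19
#'   channels.
#' @param eeg_rate Sampling rate, Hz.
#' @param noise_sd Per-channel noise standard deviation, microvolts.
#' @param spatial_mixing `"exp-distance"` (channel correlation
#'   `exp(-d/lambda)` over the schematic 10-20 layout, `lambda` = 0.4 head
#'   radii), `"none"` (independent channels), or an explicit
#'   `channels x channels` mixing matrix `M` (noise covariance
#'   `M M' * noise_sd^2`).
#' @param common_component `NULL`, or a list with `topography` (length
#'   `n_channels`), `latency` (s), `width` (Gaussian temporal SD, s) and
#'   `amplitude` (microvolts). The default is a fronto-central negativity at
#'   100 ms, the prototypical N100.
#' @param effect `NULL`, or a list with `topography_a`, `topography_b`
#'   (length `n_channels`; the built-ins are zero-mean, unit-norm left/right
#'   temporal patterns), `window` (`c(start, end)` s), `amplitude`
#'   (microvolts), `envelope` (`"cosine"` for a 10 ms cosine-ramped boxcar,
#'   or `"boxcar"`), and `categories_a` / `categories_b` (schedule categories
#'   receiving each topography).
#' @param artifact_rate Per-trial probability used by [inject_artifacts()]
#'   when driven from this config.
#' @param artifact_amplitude Artifact pulse amplitude, microvolts.
#' @param coma_mode If `TRUE`, the common component is attenuated to 30% of
#'   its amplitude and delayed by 80 ms, emulating the atypical low-amplitude,
#'   shifted-latency evoked responses seen in comatose patients.
#' @return An object of class `sim_eeg_config`.
#' @export
sim_eeg_config <- function(n_channels = 19,
                           channels = NULL,
                           eeg_rate = 1024,
                           noise_sd = 10,
                           spatial_mixing = "exp-distance",
                           common_component = default_common_component(),
                           effect = NULL,
                           artifact_rate = 0,
                           artifact_amplitude = 150,
                           coma_mode = FALSE) {
  if (is.null(channels)) {
    channels <- if (n_channels == 19) channels_1020()
                else sprintf("ch%02d", seq_len(n_channels))
  }
  stopifnot(length(channels) == n_channels, noise_sd >= 0, eeg_rate > 0)
  stop_if_not_scalar_prob(artifact_rate, "artifact_rate")

  mixing <- if (is.matrix(spatial_mixing)) {
    stopifnot(nrow(spatial_mixing) == n_channels,
              ncol(spatial_mixing) == n_channels)
    spatial_mixing
  } else if (identical(spatial_mixing, "exp-distance")) {
    t(chol(exp_distance_correlation(channels)))
  } else if (identical(spatial_mixing, "none")) {
    diag(n_channels)
  } else {
    stop("`spatial_mixing` must be a matrix, \"exp-distance\" or \"none\"",
         call. = FALSE)
  }

  if (!is.null(common_component)) {
    stopifnot(length(common_component$topography) == n_channels)
    if (coma_mode) {
      common_component$amplitude <- common_component$amplitude * 0.3
      common_component$latency <- common_component$latency + 0.08
    }
  }
  if (!is.null(effect)) {
    stopifnot(length(effect$topography_a) == n_channels,
              length(effect$topography_b) == n_channels,
              length(effect$window) == 2, effect$window[1] < effect$window[2])
    effect$envelope <- match.arg(effect$envelope %||% "cosine",
                                 c("cosine", "boxcar"))
    effect$ramp <- effect$ramp %||% 0.01
    effect$categories_a <- effect$categories_a %||% "animal"
    effect$categories_b <- effect$categories_b %||% "human"
  }

  structure(
    list(n_channels = as.integer(n_channels), channels = channels,
         eeg_rate = eeg_rate, noise_sd = noise_sd, mixing = mixing,
         common_component = common_component, effect = effect,
         artifact_rate = artifact_rate,
         artifact_amplitude = artifact_amplitude,
         coma_mode = coma_mode),
    class = "sim_eeg_config"
  )
}

#' @rdname sim_eeg_config
#' @export
default_common_component <- function() {
  list(topography = -scalp_bump("Cz", width = 0.55),
       latency = 0.1, width = 0.015, amplitude = 5)
}

#' Built-in condition-effect topographies
#'
#' Zero-mean, unit-L2-norm left- and right-temporal patterns used as the
#' default condition-specific template maps of the simulator.
#'
#' @param window Effect time window, seconds.
#' @param amplitude Effect amplitude (microvolts).
#' @param envelope `"cosine"` or `"boxcar"`.
#' @param categories_a,categories_b Schedule categories mapped to each
#'   topography.
#' @return A list suitable for the `effect` argument of [sim_eeg_config()].
#' @export
default_effect <- function(window = c(0.3, 0.4), amplitude = 1,
                           envelope = "cosine",
                           categories_a = "animal", categories_b = "human") {
  unitize <- function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) }
  list(topography_a = unitize(scalp_bump("T3") - 0.6 * scalp_bump("P4")),
       topography_b = unitize(scalp_bump("T4") - 0.6 * scalp_bump("P3")),
       window = window, amplitude = amplitude, envelope = envelope,
       categories_a = categories_a, categories_b = categories_b)
}

#' Effect amplitude giving a target single-trial topography separation
#'
#' Returns the amplitude `beta` such that the distance between the two
#' condition-mean topographies inside the effect window equals
#' `separation * noise_sd`, i.e. the class means are `separation` noise
#' standard deviations apart along the discriminant direction.
#'
#' @param cfg A [sim_eeg_config()] with a non-`NULL` `effect`.
#' @param separation Desired separation in units of per-channel noise SD.
#' @return Amplitude in microvolts.
#' @export
separation_to_amplitude <- function(cfg, separation) {
  stopifnot(inherits(cfg, "sim_eeg_config"), !is.null(cfg$effect))
  d <- sqrt(sum((cfg$effect$topography_a - cfg$effect$topography_b)^2))
  separation * cfg$noise_sd / d
}

effect_envelope <- function(times, window, envelope, ramp) {
  env <- as.numeric(times >= window[1] & times < window[2])
  if (envelope == "cosine" && ramp > 0) {
    up <- times >= window[1] & times < window[1] + ramp
    dn <- times >= window[2] - ramp & times < window[2]
    env[up] <- 0.5 * (1 - cos(pi * (times[up] - window[1]) / ramp))
    env[dn] <- 0.5 * (1 - cos(pi * (window[2] - times[dn]) / ramp))
  }
  env
}

#' Simulate single-trial epochs for a session schedule
#'
#' Each event of the schedule yields one epoch equal to the sum of the
#' common evoked component (if any), the condition effect assigned by the
#' event's category (if any), and spatially mixed Gaussian noise. The
#' ground truth (effect window, amplitude, category mapping) is retained in
#' the metadata so downstream recovery can be scored.
#'
#' @param schedule A `session_schedule` (only `category` is used).
#' @param cfg A [sim_eeg_config()].
#' @param epoch_window `c(tmin, tmax)` seconds around onset, half-open in
#'   time.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return An [epoch_set()] labelled with the schedule categories.
#' @export
simulate_epochs <- function(schedule, cfg, epoch_window = c(-0.1, 0.8), seed) {
  stopifnot(inherits(cfg, "sim_eeg_config"))
  idx <- epoch_index_grid(epoch_window[1], epoch_window[2], cfg$eeg_rate)
  times <- idx / cfg$eeg_rate
  nt <- nrow(schedule)
  nc <- cfg$n_channels
  ns <- length(times)
  labels <- schedule$category

  if (!is.null(cfg$effect)) {
    w <- cfg$effect$window
    if (w[1] < epoch_window[1] || w[2] > epoch_window[2]) {
      stop("effect window must lie inside the epoch window", call. = FALSE)
    }
  }

  base <- matrix(0, nc, ns)
  if (!is.null(cfg$common_component)) {
    cc <- cfg$common_component
    env <- cc$amplitude * exp(-(times - cc$latency)^2 / (2 * cc$width^2))
    base <- base + outer(cc$topography, env)
  }

  data <- array(0, dim = c(nt, nc, ns))
  eff_a <- eff_b <- NULL
  if (!is.null(cfg$effect)) {
    ef <- cfg$effect
    env <- ef$amplitude * effect_envelope(times, ef$window, ef$envelope, ef$ramp)
    eff_a <- outer(ef$topography_a, env)
    eff_b <- outer(ef$topography_b, env)
  }
  for (i in seq_len(nt)) {
    epo <- base
    if (!is.null(eff_a)) {
      if (labels[i] %in% cfg$effect$categories_a) epo <- epo + eff_a
      else if (labels[i] %in% cfg$effect$categories_b) epo <- epo + eff_b
    }
    data[i, , ] <- epo
  }

  if (cfg$noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(nc * ns * nt, sd = cfg$noise_sd),
                                    nrow = nc))
    noise <- cfg$mixing %*% noise
    data <- data + aperm(array(noise, dim = c(nc, ns, nt)), c(3, 1, 2))
  }

  gt <- list(
    seed = seed,
    effect_window = if (!is.null(cfg$effect)) cfg$effect$window,
    effect_amplitude = if (!is.null(cfg$effect)) cfg$effect$amplitude,
    categories_a = if (!is.null(cfg$effect)) cfg$effect$categories_a,
    categories_b = if (!is.null(cfg$effect)) cfg$effect$categories_b,
    coma_mode = cfg$coma_mode
  )
  epoch_set(data, labels, times, cfg$eeg_rate, cfg$channels,
            metadata = list(ground_truth = gt,
                            log = "simulated by simulate_epochs()"))
}

#' Inject square-pulse amplitude artifacts
#'
#' Each trial is independently selected with probability `rate`; a selected
#' trial receives a 100 ms square pulse of amplitude `+/- amplitude` added on
#' one randomly chosen channel at a random latency. The selected trial
#' indices are recorded in `metadata$artifacts`, giving downstream rejection
#' tests an exact ground truth.
#'
#' @param epochs An [epoch_set()].
#' @param rate Per-trial selection probability.
#' @param amplitude Pulse amplitude, microvolts (> 0).
#' @param seed Integer seed.
#' @return The `epoch_set` with artifacts added and ground truth recorded.
#' @export
inject_artifacts <- function(epochs, rate, amplitude, seed) {
  stopifnot(inherits(epochs, "epoch_set"), amplitude > 0)
  stop_if_not_scalar_prob(rate, "rate")
  nt <- n_trials(epochs)
  ns <- n_samples(epochs)
  pulse_len <- max(1L, min(ns, as.integer(round_half_away(0.1 * epochs$rate))))
  out <- epochs
  sel <- integer(0)
  if (rate > 0) {
    out <- with_seed(seed, {
      sel <- which(runif(nt) < rate)
      for (i in sel) {
        ch <- sample.int(n_channels(epochs), 1L)
        sgn <- sample(c(-1, 1), 1L)
        start <- sample.int(ns - pulse_len + 1L, 1L)
        span <- start:(start + pulse_len - 1L)
        epochs$data[i, ch, span] <- epochs$data[i, ch, span] + sgn * amplitude
      }
      epochs
    })
  }
  out$metadata$artifacts <- list(selected = sel, rate = rate,
                                 amplitude = amplitude)
  out
}
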