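# Shared fixtures, all generated in code.

# Small two-condition design: `n_each` trials per decoding condition.
small_design <- function(n_exemplars = 3, n_blocks = 2, repeats = 2) {
  stimulus_design(
    n_blocks = n_blocks,
    living_exemplars = data.frame(
      name = c(paste0("a", seq_len(n_exemplars)),
               paste0("h", seq_len(n_exemplars))),
      subclass = rep(c("animal", "human"), each = n_exemplars)
    ),
    manmade_exemplars = "m1",
    repeats_per_block = repeats
  )
}

# Acceptance-geometry design: 90 animal + 90 human trials (5 blocks x 9
# exemplars x 2 repeats), matching 60 CV + 30 V per condition.
recording_design <- function() small_design(n_exemplars = 9, n_blocks = 5)

# Simulated recording with the default evoked component and a condition
# effect of the given single-trial separation (0 = null recording).
simulate_recording <- function(seed, separation = 0, design = recording_design(),
                               window = c(0.3, 0.4)) {
  cfg <- sim_eeg_config(effect = default_effect(window = window))
  cfg$effect$amplitude <-
    if (separation > 0) separation_to_amplitude(cfg, separation) else 0
  simulate_epochs(make_schedule(design, eeg_rate = 1024, seed = seed),
                  cfg, seed = seed + 1)
}

# Low-resolution epochs for fast decoder unit tests: two conditions with
# mean topographies mu_a / mu_b plus white noise, at a coarse rate.
toy_epochs <- function(n_per = 12, n_channels = 6, n_samples = 32, rate = 64,
                       mu_a = NULL, mu_b = NULL, noise_sd = 1, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  if (is.null(mu_a)) mu_a <- rep(0, n_channels)
  if (is.null(mu_b)) mu_b <- rep(0, n_channels)
  data <- withr_seed({
    arr <- array(rnorm(2 * n_per * n_channels * n_samples, sd = noise_sd),
                 dim = c(2 * n_per, n_channels, n_samples))
    for (i in seq_len(n_per)) arr[i, , ] <- arr[i, , ] + mu_a
    for (i in n_per + seq_len(n_per)) arr[i, , ] <- arr[i, , ] + mu_b
    arr
  })
  epoch_set(data, rep(c("A", "B"), each = n_per),
            times = (seq_len(n_samples) - 1) / rate, rate = rate)
}

# Brute-force AUC by exhaustive pair counting.
auc_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Brute-force one-sided signed-rank p by enumerating all 2^n sign patterns.
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  hits <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    if (sum(r[signs]) >= w_obs - 1e-9) hits <- hits + 1
  }
  hits / 2^n
}

# Brute-force run selection for select_periods (non-degenerate D).
periods_oracle <- function(D, times, tq, min_dur) {
  dt <- median(diff(times))
  min_samples <- max(1L, as.integer(ceiling(min_dur / dt - 1e-9)))
  thr <- quantile(D, tq, names = FALSE)
  above <- D >= thr
  wins <- list()
  i <- 1L
  while (i <= length(D)) {
    if (above[i]) {
      j <- i
      while (j < length(D) && above[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_samples) wins[[length(wins) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(wins) == 0) {
    peak <- which.max(D)
    start <- min(max(1L, peak - (min_samples - 1L) %/% 2L),
                 length(D) - min_samples + 1L)
    wins <- list(c(start, start + min_samples - 1L))
  }
  do.call(rbind, wins)
}
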